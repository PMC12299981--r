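BEGIN IONS
TITLE=12-hydroxy-39-O-desmethyl
PEPMASS=938.522683
CHARGE=1+
259.169084 40.260756
320.109884 100.000000
331.188111 100.000000
357.203201 100.000000
367.224842 100.000000
383.219299 100.000000
389.229934 100.000000
395.219612 100.000000
399.250778 100.000000
413.266123 100.000000
441.261417 100.000000
443.643427 13.292611
459.272211 100.000000
469.219847 100.000000
501.245577 100.000000
593.381190 100.000000
598.298047 100.000000
614.329631 100.000000
628.310083 100.000000
645.885956 32.992418
653.222753 16.920323
689.440006 100.000000
697.429749 100.000000
717.434073 100.000000
765.456042 100.000000
851.569851 25.754431
938.522683 100.000000
END IONS
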