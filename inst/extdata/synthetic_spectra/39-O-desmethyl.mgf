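BEGIN IONS
TITLE=39-O-desmethyl
PEPMASS=922.528904
CHARGE=1+
151.845231 5.282139
230.537802 40.246289
320.110985 100.000000
331.188135 100.000000
367.225146 100.000000
383.219505 100.000000
395.219378 100.000000
399.250186 100.000000
413.265692 100.000000
441.260945 100.000000
453.224509 100.000000
459.271615 100.000000
475.111210 38.569234
485.250639 100.000000
582.304317 100.000000
593.381609 100.000000
614.330213 100.000000
622.081537 10.194606
628.309361 100.000000
689.438998 100.000000
717.433281 100.000000
749.460152 100.000000
922.528904 100.000000
925.854431 12.287237
END IONS
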