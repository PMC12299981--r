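BEGIN IONS
TITLE=hydroxy-piperidine-39-O-desmethyl
PEPMASS=938.524092
CHARGE=1+
331.187775 100.000000
336.104933 100.000000
336.104960 100.000000
367.224027 100.000000
378.937702 39.546330
383.218867 100.000000
395.218991 100.000000
399.250314 100.000000
413.266137 100.000000
441.261394 100.000000
459.271181 100.000000
469.220487 100.000000
501.246218 100.000000
581.493204 48.309887
593.381364 100.000000
598.298730 100.000000
614.330293 100.000000
628.308883 100.000000
638.352297 41.238874
677.286674 21.269086
689.439541 100.000000
717.433294 100.000000
749.459905 100.000000
938.524092 100.000000
985.426872 26.955678
END IONS
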