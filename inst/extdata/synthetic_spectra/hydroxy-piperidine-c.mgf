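BEGIN IONS
TITLE=hydroxy-piperidine-c
PEPMASS=952.538552
CHARGE=1+
274.860155 9.445830
284.251867 24.152568
336.105510 100.000000
336.105673 100.000000
345.203207 100.000000
381.240326 100.000000
395.072899 30.152130
397.235243 100.000000
399.251006 100.000000
409.235134 100.000000
413.266471 100.000000
441.261005 100.000000
459.271468 100.000000
469.219802 100.000000
501.246351 100.000000
598.298662 100.000000
607.396041 100.000000
614.329539 100.000000
642.325512 100.000000
703.453019 100.000000
731.448552 100.000000
763.476584 100.000000
856.039701 47.731650
952.538552 100.000000
992.938430 31.773144
END IONS
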