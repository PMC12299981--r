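BEGIN IONS
TITLE=12-hydroxy
PEPMASS=952.539799
CHARGE=1+
185.509370 47.165795
320.110690 100.000000
345.203766 100.000000
357.202867 100.000000
381.240165 100.000000
389.229092 100.000000
397.234747 100.000000
399.250138 100.000000
409.235059 100.000000
413.265451 100.000000
441.260757 100.000000
459.271847 100.000000
469.219609 100.000000
501.246415 100.000000
509.131833 36.235591
598.298086 100.000000
607.396923 100.000000
614.330183 100.000000
642.324361 100.000000
678.496777 11.492587
703.453606 100.000000
711.443526 100.000000
731.449282 100.000000
779.471770 100.000000
881.025381 23.042366
902.986639 7.310228
952.539799 100.000000
END IONS
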