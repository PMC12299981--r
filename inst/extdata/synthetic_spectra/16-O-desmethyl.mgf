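BEGIN IONS
TITLE=16-O-desmethyl
PEPMASS=922.529129
CHARGE=1+
306.793033 48.968540
320.110492 100.000000
345.204161 100.000000
381.240412 100.000000
385.234950 100.000000
397.235514 100.000000
409.235091 100.000000
413.266415 100.000000
441.260438 100.000000
453.224897 100.000000
459.271620 100.000000
471.235154 100.000000
546.413421 49.258681
568.287348 100.000000
607.397110 100.000000
614.329271 100.000000
618.775396 45.933942
642.325372 100.000000
675.034272 30.715884
689.439396 100.000000
717.434664 100.000000
749.460451 100.000000
780.944702 25.568303
922.529129 100.000000
END IONS
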