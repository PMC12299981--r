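BEGIN IONS
TITLE=27-O-desmethyl
PEPMASS=922.530536
CHARGE=1+
320.110391 100.000000
345.203260 100.000000
375.681472 34.493361
381.240113 100.000000
397.235298 100.000000
399.250202 100.000000
399.250523 100.000000
409.234433 100.000000
425.542652 19.593803
427.245647 100.000000
445.256169 100.000000
453.224876 100.000000
485.250835 100.000000
572.073582 19.024721
582.304399 100.000000
593.382254 100.000000
600.314242 100.000000
642.324302 100.000000
689.438331 100.000000
717.432821 100.000000
738.438062 5.133027
749.458291 100.000000
753.944147 10.824207
922.530536 100.000000
END IONS
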