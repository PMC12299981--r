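BEGIN IONS
TITLE=27,39-O-didesmethyl
PEPMASS=908.513788
CHARGE=1+
175.131563 26.927019
320.110877 100.000000
331.188137 100.000000
340.143947 12.611848
367.224112 100.000000
383.219061 100.000000
395.219312 100.000000
399.249854 100.000000
399.250579 100.000000
427.245100 100.000000
445.256475 100.000000
453.224803 100.000000
485.251231 100.000000
579.365596 100.000000
582.303544 100.000000
600.314099 100.000000
615.172333 21.208286
628.309499 100.000000
675.422535 100.000000
698.520255 9.883171
703.417567 100.000000
735.444049 100.000000
908.513788 100.000000
986.465596 12.996777
END IONS
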