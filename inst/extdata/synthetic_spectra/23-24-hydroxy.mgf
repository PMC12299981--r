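BEGIN IONS
TITLE=23/24-hydroxy
PEPMASS=952.539046
CHARGE=1+
298.518370 27.977744
320.109915 100.000000
345.203831 100.000000
381.240105 100.000000
397.234984 100.000000
399.250273 100.000000
409.234670 100.000000
411.250561 150.000000
429.261245 100.000000
439.244781 150.000000
453.224804 100.000000
457.255842 100.000000
457.255988 150.000000
475.265631 100.000000
485.250642 100.000000
509.429521 11.287119
582.303770 100.000000
605.382062 150.000000
612.315401 150.000000
623.391206 100.000000
630.324163 100.000000
642.325416 100.000000
656.481582 25.484296
701.438700 150.000000
719.450596 100.000000
729.433446 150.000000
747.443945 100.000000
761.462052 150.000000
779.469712 100.000000
801.263649 35.446698
913.523408 7.001142
934.529046 150.000000
952.539046 100.000000
END IONS
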