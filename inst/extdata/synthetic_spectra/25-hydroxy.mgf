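BEGIN IONS
TITLE=25-hydroxy
PEPMASS=952.539433
CHARGE=1+
204.587230 28.133512
320.110568 100.000000
327.192481 100.000000
345.203174 100.000000
381.239493 100.000000
397.234567 100.000000
399.250288 100.000000
409.234736 100.000000
429.261759 100.000000
447.271901 100.000000
453.225377 100.000000
457.255842 100.000000
475.266744 100.000000
485.250666 100.000000
582.303617 100.000000
598.943142 14.848383
607.303953 31.939949
623.392974 100.000000
630.325909 100.000000
642.324083 100.000000
719.448815 100.000000
747.443955 100.000000
779.470564 100.000000
866.708245 16.120533
952.539433 100.000000
999.945869 26.841495
END IONS
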