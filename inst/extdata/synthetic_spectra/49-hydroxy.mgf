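BEGIN IONS
TITLE=49-hydroxy
PEPMASS=952.540372
CHARGE=1+
163.972281 39.772340
320.110049 100.000000
361.197584 100.000000
361.198446 100.000000
397.234688 100.000000
397.234947 100.000000
399.250885 100.000000
402.702789 13.034026
409.234880 100.000000
413.266858 100.000000
441.261253 100.000000
453.225137 100.000000
459.271651 100.000000
480.110965 41.940064
485.251072 100.000000
491.075385 20.474487
582.303749 100.000000
614.328681 100.000000
623.391570 100.000000
642.323991 100.000000
719.448996 100.000000
747.443955 100.000000
779.472107 100.000000
872.549685 30.095250
952.540372 100.000000
END IONS
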