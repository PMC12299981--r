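BEGIN IONS
TITLE=12,23/24-dihydroxy
PEPMASS=968.531187
CHARGE=1+
320.110511 100.000000
345.203330 100.000000
357.202806 100.000000
372.757874 27.912283
381.240363 100.000000
397.234673 100.000000
399.250680 100.000000
405.224451 100.000000
409.234356 100.000000
411.250275 150.000000
429.260920 100.000000
439.245789 150.000000
457.255419 150.000000
457.256254 100.000000
461.780753 36.227072
469.219256 100.000000
469.287369 7.831831
475.266655 100.000000
501.245573 100.000000
522.743616 34.516329
580.604260 40.767656
598.298356 100.000000
605.381068 150.000000
612.314521 150.000000
623.391343 100.000000
630.325075 100.000000
642.324959 100.000000
701.437642 150.000000
719.450236 100.000000
727.440139 100.000000
729.434220 150.000000
747.443301 100.000000
777.454245 150.000000
795.464052 100.000000
950.523559 150.000000
968.531187 100.000000
END IONS
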