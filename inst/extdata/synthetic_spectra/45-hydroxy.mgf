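BEGIN IONS
TITLE=45-hydroxy
PEPMASS=952.539568
CHARGE=1+
203.188769 7.955158
320.110436 100.000000
345.203341 100.000000
381.240093 100.000000
397.234110 100.000000
399.251139 100.000000
409.234995 100.000000
413.266034 100.000000
441.260330 100.000000
453.224514 100.000000
459.271931 100.000000
485.251570 100.000000
582.303533 100.000000
591.365505 50.000000
614.330604 100.000000
623.391744 100.000000
626.294674 50.000000
658.320553 100.000000
682.489265 33.070623
687.422350 50.000000
695.813586 41.560175
715.417946 50.000000
719.450047 100.000000
747.443128 100.000000
747.444705 50.000000
779.470443 100.000000
856.332665 17.158159
920.512984 50.000000
952.539568 100.000000
956.136172 31.504288
END IONS
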