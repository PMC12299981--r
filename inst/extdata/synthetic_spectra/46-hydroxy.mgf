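BEGIN IONS
TITLE=46-hydroxy
PEPMASS=952.539186
CHARGE=1+
156.933686 10.921909
182.337881 44.774657
316.177992 13.853792
320.110710 100.000000
345.203975 100.000000
381.240090 100.000000
397.234629 100.000000
399.250522 100.000000
409.234585 100.000000
413.266792 100.000000
441.261322 100.000000
453.224434 100.000000
459.271590 100.000000
485.251175 100.000000
582.304076 100.000000
591.365404 50.000000
614.330243 100.000000
619.000952 13.891926
623.391324 100.000000
626.293212 50.000000
658.318842 100.000000
673.959707 21.747808
687.423398 50.000000
715.418605 50.000000
719.449247 100.000000
747.443449 100.000000
747.443697 50.000000
779.471479 100.000000
920.511603 50.000000
952.539186 100.000000
END IONS
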