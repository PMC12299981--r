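BEGIN IONS
TITLE=hydroxy-piperidine-a
PEPMASS=952.539604
CHARGE=1+
252.519406 20.096443
336.104280 100.000000
336.105154 100.000000
345.203806 100.000000
381.240394 100.000000
397.235578 100.000000
399.249271 100.000000
409.235313 100.000000
413.265638 100.000000
441.261363 100.000000
459.271831 100.000000
469.220514 100.000000
499.063268 47.554812
501.246232 100.000000
598.298377 100.000000
606.852737 8.875181
607.397704 100.000000
614.329602 100.000000
621.023938 41.438122
642.324500 100.000000
703.454656 100.000000
731.449162 100.000000
763.475182 100.000000
859.798073 12.774009
952.539604 100.000000
END IONS
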