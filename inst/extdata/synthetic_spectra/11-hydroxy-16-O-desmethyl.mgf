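BEGIN IONS
TITLE=11-hydroxy-16-O-desmethyl
PEPMASS=938.523746
CHARGE=1+
206.619435 22.022723
320.110632 100.000000
345.203302 100.000000
381.240115 100.000000
385.235173 100.000000
397.234973 100.000000
409.234445 100.000000
413.267201 100.000000
421.779732 42.939935
436.833730 31.606085
441.261821 100.000000
459.271634 100.000000
469.218782 100.000000
487.229352 100.000000
584.283360 100.000000
598.078697 18.801608
607.396790 100.000000
614.329954 100.000000
642.324098 100.000000
689.438990 100.000000
709.465025 100.000000
717.432952 100.000000
765.454411 100.000000
901.171675 7.677181
938.523746 100.000000
END IONS
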