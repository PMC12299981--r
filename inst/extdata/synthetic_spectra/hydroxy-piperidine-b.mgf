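BEGIN IONS
TITLE=hydroxy-piperidine-b
PEPMASS=952.540646
CHARGE=1+
246.890790 21.240504
319.312843 30.986671
336.104758 100.000000
336.105573 100.000000
345.204157 100.000000
381.239626 100.000000
397.234745 100.000000
399.250171 100.000000
409.234740 100.000000
413.266769 100.000000
441.260387 100.000000
459.271258 100.000000
469.218971 100.000000
501.245800 100.000000
598.298309 100.000000
607.396482 100.000000
614.330576 100.000000
642.324170 100.000000
703.453599 100.000000
731.449630 100.000000
763.475543 100.000000
799.075243 12.304934
914.308033 7.698653
952.540646 100.000000
964.777498 34.246516
END IONS
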