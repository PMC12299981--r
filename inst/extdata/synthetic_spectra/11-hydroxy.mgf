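BEGIN IONS
TITLE=11-hydroxy
PEPMASS=952.539316
CHARGE=1+
172.087400 25.988685
218.197780 44.250403
221.917723 41.707240
273.023020 43.051833
320.109690 100.000000
345.203712 100.000000
381.240265 100.000000
397.235167 100.000000
399.250276 100.000000
409.235855 100.000000
413.266536 100.000000
441.260880 100.000000
459.271642 100.000000
469.219024 100.000000
501.245607 100.000000
598.298502 100.000000
607.398192 100.000000
612.349256 35.185280
614.329766 100.000000
642.325270 100.000000
703.455015 100.000000
723.480862 100.000000
731.449829 100.000000
779.470328 100.000000
952.539316 100.000000
END IONS
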