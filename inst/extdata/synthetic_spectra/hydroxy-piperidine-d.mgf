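BEGIN IONS
TITLE=hydroxy-piperidine-d
PEPMASS=952.540403
CHARGE=1+
336.104789 100.000000
336.105843 100.000000
345.203791 100.000000
381.239781 100.000000
397.234566 100.000000
399.250617 100.000000
409.234798 100.000000
413.266016 100.000000
441.260880 100.000000
459.271904 100.000000
469.219419 100.000000
501.245204 100.000000
598.298187 100.000000
607.396512 100.000000
614.331356 100.000000
642.324798 100.000000
642.543290 42.535824
688.662767 12.626658
703.453758 100.000000
731.448472 100.000000
763.475677 100.000000
767.228415 45.331501
815.415968 45.999328
842.705966 24.559705
952.540403 100.000000
END IONS
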