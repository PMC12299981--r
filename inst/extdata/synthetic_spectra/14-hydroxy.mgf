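BEGIN IONS
TITLE=14-hydroxy
PEPMASS=952.539556
CHARGE=1+
320.110879 100.000000
345.203079 100.000000
381.239977 100.000000
395.461460 36.719800
397.234566 100.000000
409.235483 100.000000
413.267260 100.000000
415.245196 100.000000
441.261774 100.000000
459.271172 100.000000
469.219864 100.000000
501.245724 100.000000
524.592356 25.928528
598.298414 100.000000
607.396822 100.000000
612.313512 100.000000
614.329571 100.000000
642.323861 100.000000
703.453594 100.000000
747.445844 100.000000
779.470589 100.000000
820.082353 15.065407
847.417428 22.480853
931.273709 25.121027
952.539556 100.000000
END IONS
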