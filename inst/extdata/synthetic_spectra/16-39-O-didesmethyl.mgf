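BEGIN IONS
TITLE=16,39-O-didesmethyl
PEPMASS=908.513357
CHARGE=1+
234.710104 28.387883
320.110658 100.000000
331.187808 100.000000
367.224743 100.000000
383.218984 100.000000
385.234995 100.000000
395.219025 100.000000
413.266621 100.000000
441.261686 100.000000
453.224881 100.000000
459.272037 100.000000
471.235013 100.000000
568.288006 100.000000
572.689105 44.786471
593.380627 100.000000
614.329202 100.000000
628.309729 100.000000
653.423167 15.693712
659.423416 42.795454
675.424704 100.000000
703.418052 100.000000
735.444725 100.000000
796.518781 34.458520
908.513357 100.000000
END IONS
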