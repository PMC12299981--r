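# Sirolimus sodiated fragment library: alpha-cleavage fragments A-R plus
# the molecular ion and the hydroxylation-diagnostic ions.
# Columns:
#   label    - fragment identifier
#   mz       - theoretical m/z of the sodiated ion. Anchor fragments K, C,
#              D, G, O carry reconstructed extra decimals chosen to be
#              jointly consistent with the published 4-dp parent AND
#              shifted-fragment masses; all others are the published 4-dp
#              values. The molecular-ion mass is recomputed from the
#              elemental formula at load time.
#   kind     - molecular_ion | alpha_cleavage | hydroxylation_diagnostic
#   parent   - MS^n parent in the fragmentation tree
#   site     - diagnostic carbon position (diagnostics only)
#   coverage - covered carbon positions (ranges; "pip" = piperidine C3-C6).
#              Main-text anchors are exact; the remaining extents are
#              synthetic reconstructions (the per-fragment carbon ranges are
#              published only in the source appendix) satisfying the
#              fragmentation-tree subset invariant and every main-text
#              inclusion/exclusion statement.
# Notes on known print discrepancies in the source tables: the
# 27-O-desmethyl molecular ion is printed once as 922.5887 (computed and
# stored logic uses 922.5287, like every other demethylated ion); the
# hydroxylated fragment O is printed both as 457.2561 and 457.2556 (the
# stored mass is consistent with 457.2561); its printed water-loss partner
# 439.2449 computes to 439.2455 and is not asserted anywhere.
label,mz,kind,parent,site,coverage
SRL,936.544362,molecular_ion,,,"1-52,pip"
A,731.4493,alpha_cleavage,B,,"14-52"
B,763.4756,alpha_cleavage,SRL,,"10-52"
C,642.324875,alpha_cleavage,E,,"28-46"
D,345.203625,alpha_cleavage,K,,"36-44,47-49,51-52"
E,703.4544,alpha_cleavage,A,,"16-52"
F,399.2506,alpha_cleavage,A,,"14-21"
G,614.330018,alpha_cleavage,E,,"18-27"
H,485.2510,alpha_cleavage,M,,"1-16,pip"
I,459.2717,alpha_cleavage,K,,"17-30"
J,409.2349,alpha_cleavage,K,,"30-44"
K,607.396918,alpha_cleavage,E,,"17-49,51-52"
L,397.2349,alpha_cleavage,C,,"33-44"
M,582.3037,alpha_cleavage,SRL,,"1-17,pip"
N,453.2248,alpha_cleavage,H,,"1-14,pip"
O,441.261143,alpha_cleavage,G,,"20-27"
P,381.2400,alpha_cleavage,K,,"37-44,47-49"
Q,320.1105,alpha_cleavage,N,,"1-9,pip"
R,413.2662,alpha_cleavage,I,,"21-30"
OH11-diag,723.4806,hydroxylation_diagnostic,SRL,11,"14-44"
OH12-diag-a,711.4442,hydroxylation_diagnostic,SRL,12,"14-44"
OH12-diag-b,389.2293,hydroxylation_diagnostic,SRL,12,"18-30"
OH12-diag-c,357.2031,hydroxylation_diagnostic,SRL,12,
OH14-diag,612.3133,hydroxylation_diagnostic,SRL,14,
OH25-diag-a,447.2718,hydroxylation_diagnostic,SRL,25,
OH25-diag-b,327.1922,hydroxylation_diagnostic,SRL,25,
OH49-diag,361.1978,hydroxylation_diagnostic,SRL,49,
OHpip-diag,336.1050,hydroxylation_diagnostic,SRL,pip,
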