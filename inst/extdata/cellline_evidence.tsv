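# External evidence for the NSCLC cell-line ND variants. Boolean flags
# encode the qualitative reported findings (SWISS-MODEL conformational
# change, MITOMAP disease association, MitoSOX mtROS overproduction,
# conservation of the original residue). The MutPred value for m.11453G>A
# is a synthetic stand-in for a score reported only as "high" (> 0.7);
# fields left empty are evidence not reported.
sample	position	alt	mutpred	conserved	conformational_change	disease_associated	mtros_overproduction
H358	13708	A			TRUE	TRUE	TRUE
H358	4216	C				TRUE
RERF-Lc-Ad2	11453	A	0.75	TRUE			TRUE
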