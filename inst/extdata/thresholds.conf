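# Default growth-class thresholds (implementation defaults; the original
# PMAnalyzer cutoffs are not published). Cutoffs are inclusive lower
# bounds of each class above the lowest. GS cutoffs are the GL cutoffs
# mapped through the GS-on-GL regression line of a default simulated
# cohort (seed 1), so the two label sets are comparable.
labels = -, +, ++, +++, ++++
gl_cutoffs = 0.25, 0.75, 1.25, 1.75
gs_cutoffs = 0.2115, 0.5428, 0.8740, 1.2053
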