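# Two codesigned transition seeds, weight 8, span 8..12, designed by
# subseed::design_seeds() for the Bernoulli model (0.12, 0.18, 0.70)
# (70% identity, 3:2 transition:transversion), l = 64, 30 restarts,
# rng_seed 20260920. Joint sensitivity 0.9520360.
11T01011TTT1
T1T10TT01111
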