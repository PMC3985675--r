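# Single transition seed, weight 8, span 8..12, designed by
# subseed::design_seeds() for the Bernoulli model (0.12, 0.18, 0.70),
# l = 64, 30 restarts, rng_seed 20260920. Sensitivity 0.8883247.
11TT0101TT11
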