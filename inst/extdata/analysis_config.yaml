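# analysis configuration for the shipped planar demo city
radii_m: [1000, 2500, 5000]
distance_metric: euclidean
traditional_variant: per_household
min_communities: 2
seed: 1
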