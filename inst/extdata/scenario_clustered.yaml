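# simulate scenario: green space concentrated near one focus, prices coupled
# to green proximity (ugsaccess.R simulate --config ... --seed ... --out ...)
n_cities: 5
n_communities: 200
n_greenspots: 25
extent_m: 20000
layout: uniform
green_cluster: 4
price_gamma: 0.3
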