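# Demo facet-gradient configuration: a ~247-facet eye with the measured
# diameter envelope, largest facets anteroventral, smallest posteroventral,
# and a +12 right-minus-left count asymmetry.
base_diameter: 11.8
anteroventral_excess: 1.0
posteroventral_deficit: 1.5
noise_sd: 0.3
target_count: 247
asymmetry: 12
seed: 1
diameter_range: [9.3, 13.7]
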