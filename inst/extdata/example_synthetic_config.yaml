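n_strata: 4.0
psus_per_stratum: 6.0
households_per_psu: 30.0
asset_count: 6.0
psu_effect_sd: 0.3
weight_scheme: uniform
partner_missing_rate: 0.02
seed: 1.0
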