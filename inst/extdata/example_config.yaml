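# Example override config for load_reference(): keys match reference_params()
# fields; units are fixed per field (see param_units()).
turgor_pressure: 0.65
valve_width: 2.5
n_seeds: 12
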