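latitude: 11.41
elevation: 2218
albedo: 0.23
angstrom_a: 0.25
angstrom_b: 0.50
pan_fetch: 100
anemometer_height: 2
latent_heat: 2.45
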