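# one shared, moderately sized RD calibration for the classification tests
# (the acceptance checks build their own full-size calibration)
shared_calib <- calibrate_rd_cutoffs(n_per_length = 300, seed = 4242)
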