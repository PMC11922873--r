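drug	n_reports
BSZ	1455
CD	7289
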