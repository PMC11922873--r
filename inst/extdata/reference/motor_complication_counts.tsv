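endpoint	count_total	count_bsz	count_cd
dyskinesia	1556	342	1214
wearing_off	724	64	660
on_off_phenomenon	418	157	261
freezing_phenomenon	356	77	279
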