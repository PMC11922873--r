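endpoint	pattern	match_mode
dyskinesia	dyskinesia	keyword_substring
dyskinesia	dystonia	keyword_substring
dyskinesia	hyperkinesia	keyword_substring
dyskinesia	ballismus	keyword_substring
dyskinesia	alien limb syndrome	keyword_substring
wearing_off	therapeutic response shortened	keyword_substring
wearing_off	therapeutic response incomplete	keyword_substring
on_off_phenomenon	On and off phenomenon	exact_pt
freezing_phenomenon	Freezing phenomenon	exact_pt
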