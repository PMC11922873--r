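raw	canonical
ORAL	oral
PO	oral
MOUTH	oral
ORAL, UNSPECIFIED	oral
INTRADUODENAL	intraduodenal
INTESTINAL INFUSION	intestinal_infusion
INTRAJEJUNAL	intestinal_infusion
TRANSDERMAL	transdermal
INTRAVENOUS	intravenous
INTRAVENOUS DRIP	intravenous
INTRAVENOUS (NOT OTHERWISE SPECIFIED)	intravenous
SUBCUTANEOUS	subcutaneous
INTRAMUSCULAR	intramuscular
RECTAL	rectal
NASOGASTRIC TUBE	enteral
UNKNOWN	unknown
UNSPECIFIED	unknown
UNK	unknown
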