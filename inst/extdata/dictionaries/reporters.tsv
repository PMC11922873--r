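code	label
MD	physician
CN	consumer
OT	other_health_professional
HP	other_health_professional
RN	other_health_professional
PH	pharmacist
LW	lawyer
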