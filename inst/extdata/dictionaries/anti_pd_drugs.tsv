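drug
pramipexole
amantadine
rasagiline
ropinirole
rotigotine
entacapone
selegiline
opicapone
safinamide
apomorphine
tolcapone
bromocriptine
piribedil
istradefylline
trihexyphenidyl
benztropine
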