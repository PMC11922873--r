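code	group
US	United States
JP	Japan
DE	Europe
FR	Europe
GB	Europe
IT	Europe
ES	Europe
NL	Europe
BE	Europe
CH	Europe
AT	Europe
SE	Europe
NO	Europe
DK	Europe
FI	Europe
PT	Europe
IE	Europe
PL	Europe
CZ	Europe
GR	Europe
HU	Europe
RO	Europe
SK	Europe
SI	Europe
HR	Europe
BG	Europe
EE	Europe
LV	Europe
LT	Europe
LU	Europe
MT	Europe
CY	Europe
IS	Europe
BR	South America
AR	South America
CL	South America
CO	South America
PE	South America
VE	South America
UY	South America
PY	South America
EC	South America
BO	South America
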