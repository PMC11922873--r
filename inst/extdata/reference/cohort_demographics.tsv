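drug	variable	level	count
BSZ	age	<20	2
BSZ	age	20-50	26
BSZ	age	50-65	178
BSZ	age	>=65	930
BSZ	age	unknown	319
BSZ	reporter	physician	407
BSZ	reporter	consumer	388
BSZ	reporter	other_health_professional	303
BSZ	reporter	pharmacist	298
BSZ	reporter	unknown	59
BSZ	reporter	lawyer	0
BSZ	outcome	hospitalization	906
BSZ	outcome	other_serious	649
BSZ	outcome	life_threatening_death	353
BSZ	outcome	disability	50
BSZ	outcome	congenital_anomaly	1
BSZ	country	Europe	675
BSZ	country	United States	0
BSZ	country	Japan	78
BSZ	country	South America	65
BSZ	country	other	637
BSZ	sex	female	633
BSZ	sex	male	789
BSZ	sex	unknown	33
CD	age	<20	2
CD	age	20-50	147
CD	age	50-65	945
CD	age	>=65	3788
CD	age	unknown	2407
CD	reporter	physician	999
CD	reporter	consumer	5127
CD	reporter	other_health_professional	528
CD	reporter	pharmacist	519
CD	reporter	unknown	113
CD	reporter	lawyer	3
CD	outcome	hospitalization	1790
CD	outcome	other_serious	1843
CD	outcome	life_threatening_death	709
CD	outcome	disability	228
CD	outcome	congenital_anomaly	1
CD	country	Europe	650
CD	country	United States	5141
CD	country	Japan	248
CD	country	South America	50
CD	country	other	1200
CD	sex	female	3429
CD	sex	male	3703
CD	sex	unknown	157
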