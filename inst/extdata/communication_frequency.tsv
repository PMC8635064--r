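# phrase	times_per_month
every day	30
everyday	30
daily	30
twice a day	60
most days	20
several times a week	12
a few times a week	12
twice a week	8.66
every week	4.33
once a week	4.33
weekly	4.33
every other week	2.17
couple times a month	2
a couple of times a month	2
twice a month	2
once a month	1
every month	1
monthly	1
once in a while	0.5
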