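drug	rank
compound 15	0
carvedilol	1
nebivolol	2
labetalol	3
atenolol	4
metoprolol	5
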