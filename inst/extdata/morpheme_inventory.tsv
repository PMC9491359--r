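text	role	subset	child_subset	old20
help	stem	A	A	1.00
soft	stem	A	A	1.00
last	stem	A	A	1.00
ship	stem	A	B	1.00
stop	stem	A	B	1.00
hold	stem	A	B	1.00
park	stem	B		1.00
jump	stem	B		1.00
town	stem	B		1.00
bird	stem	B		1.00
farm	stem	B		1.00
milk	stem	B		1.00
josk	nonstem	A	A	1.55
terp	nonstem	A	A	1.00
firn	nonstem	A	A	1.00
bron	nonstem	A	B	1.00
trum	nonstem	A	B	1.00
burk	nonstem	A	B	1.00
molp	nonstem	B		1.40
lort	nonstem	B		1.00
bemp	nonstem	B		1.40
jelt	nonstem	B		1.00
culp	nonstem	B		1.35
tand	nonstem	B		1.00
ity	suffix	A	A	1.00
ive	suffix	A	A	1.00
ory	suffix	A	A	1.00
ure	suffix	A	B	1.00
ous	suffix	A	B	1.00
ise	suffix	A	B	1.00
ful	suffix	B		1.00
ist	suffix	B		1.00
ite	suffix	B		1.00
ish	suffix	B		1.00
ese	suffix	B		1.00
ess	suffix	B		1.00
ert	nonsuffix	A	A	1.00
une	nonsuffix	A	A	1.00
ute	nonsuffix	A	A	1.00
int	nonsuffix	A	B	1.00
ald	nonsuffix	A	B	1.00
ere	nonsuffix	A	B	1.00
sal	nonsuffix	B		1.00
arn	nonsuffix	B		1.00
ene	nonsuffix	B		1.00
ult	nonsuffix	B		1.00
oke	nonsuffix	B		1.00
ust	nonsuffix	B		1.00
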