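characteristic	level	positive	negative
response	responder	7	7
response	non_responder	0	7
sex	male	6	13
sex	female	1	1
age	lt60	3	9
age	ge60	4	5
smoking	no	2	3
smoking	yes	5	11
drinking	no	3	3
drinking	yes	4	11
family_history	no	7	12
family_history	yes	0	2
tumor_length	le3cm	2	6
tumor_length	gt3cm	5	8
differentiation	low	2	6
differentiation	middle	5	7
differentiation	high	0	1
stage	I+II	0	1
stage	III+IV	7	13
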