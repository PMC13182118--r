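gene	name	substitutions	note
CSN1S1	B		synthetic fixture
CSN1S1	C	22:S>R	synthetic fixture
CSN1S1	D	22:S>R;31:H>P	synthetic fixture
CSN1S1	E	40:G>E	synthetic fixture
CSN1S2	A		synthetic fixture
CSN1S2	B	22:S>R	synthetic fixture
CSN1S2	C	40:G>E	synthetic fixture
CSN1S2	D	22:S>R;31:H>P	synthetic fixture
CSN2	A1	36:S>R	synthetic fixture
CSN2	A2	36:S>R;67:H>P	synthetic fixture
CSN2	B		synthetic fixture
CSN2	C	80:G>E	synthetic fixture
CSN3	A	50:S>R	synthetic fixture
CSN3	B		synthetic fixture
CSN3	E	50:S>R;136:H>P	synthetic fixture
CSN3	H	149:G>E	synthetic fixture
LALBA	A	8:S>R	synthetic fixture
LALBA	B		synthetic fixture
LALBA	E	8:S>R;14:H>P	synthetic fixture
LALBA	F	19:G>E	synthetic fixture
PAEP	A	20:S>R	synthetic fixture
PAEP	B		synthetic fixture
PAEP	C	20:S>R;30:H>P	synthetic fixture
PAEP	D	40:G>E	synthetic fixture
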