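transformation	variant	ddG_kJmol	se_kJmol
OMe->OH	RH/SP	0.2	0.4
OMe->OH	RH/LP	1.0	0.7
OMe->OH	BA/SP	-0.8	0.4
OMe->OH	BA/LP	1.6	0.6
OMe->OH	BH/SP	-0.6	0.4
OMe->OH	BH/LP	0.9	0.6
NHMe->OMe	RH/SP	-0.8	0.3
NHMe->OMe	RH/LP	-3.3	0.6
NHMe->OMe	BA/SP	-6.0	0.4
NHMe->OMe	BA/LP	-4.8	0.6
NHMe->OMe	BH/SP	-6.7	0.4
NHMe->OMe	BH/LP	-6.4	0.6
NMe2->NHMe	RH/SP	-5.8	0.5
NMe2->NHMe	RH/LP	-4.4	0.7
NMe2->NHMe	BA/SP	-1.6	0.5
NMe2->NHMe	BA/LP	-1.1	0.6
NMe2->NHMe	BH/SP	-3.2	0.5
NMe2->NHMe	BH/LP	-2.2	0.7
NMe2->NH2	RH/SP	-1.7	0.5
NMe2->NH2	RH/LP	-2.9	0.7
NMe2->NH2	BA/SP	-3.9	0.5
NMe2->NH2	BA/LP	-3.6	0.7
NMe2->NH2	BH/SP	-2.9	0.5
NMe2->NH2	BH/LP	-5.1	0.7
OEt->OMe	RH/SP	-2.8	0.4
OEt->OMe	RH/LP	2.7	0.7
OEt->OMe	BA/SP	-4.2	0.4
OEt->OMe	BA/LP	-1.4	0.6
OEt->OMe	BH/SP	-3.3	0.4
OEt->OMe	BH/LP	-2.7	0.6
Pyr->F	RH/SP	-10.4	0.6
Pyr->F	RH/LP	-7.5	0.8
Pyr->F	BA/SP	-10.4	0.6
Pyr->F	BA/LP	-9.1	0.7
Pyr->F	BH/SP	-9.0	0.6
Pyr->F	BH/LP	-8.3	0.7
OH->F	RH/SP	-0.4	0.2
OH->F	RH/LP	-2.1	0.6
OH->F	BA/SP	1.7	0.2
OH->F	BA/LP	-1.0	0.5
OH->F	BH/SP	1.0	0.2
OH->F	BH/LP	-0.4	0.6
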