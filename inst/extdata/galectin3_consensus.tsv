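transformation	ddG_kJmol	se_kJmol
OMe->OH	0.4	0.4
NHMe->OMe	-4.7	0.9
NMe2->NHMe	-3.0	0.7
NMe2->NH2	-3.3	0.5
OEt->OMe	-1.9	1.0
Pyr->F	-9.1	0.5
OH->F	-0.2	0.6
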