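transformation	ddG_kJmol	se_kJmol
OMe->OH	0.6	0.3
NHMe->OMe	0.0	0.3
NMe2->NHMe	-2.0	0.2
NMe2->NH2	-3.2	0.2
OEt->OMe	-4.0	0.4
Pyr->F	-11.2	NA
OH->F	-4.8	0.2
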