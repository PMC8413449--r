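position	ref	alt	label
1494	C	T	MT-RNR1 aminoglycoside-induced deafness
1555	A	G	MT-RNR1 nonsyndromic deafness
3243	A	G	MT-TL1 MELAS
3256	C	T	MT-TL1 MELAS
3271	T	C	MT-TL1 MELAS
3460	G	A	MT-ND1 LHON
3697	G	A	MT-ND1 MELAS/Leigh
3733	G	A	MT-ND1 LHON
4171	C	A	MT-ND1 LHON
5703	G	A	MT-TN myopathy
7445	A	G	MT-CO1/MT-TS1 deafness
8344	A	G	MT-TK MERRF
8356	T	C	MT-TK MERRF
8363	G	A	MT-TK cardiomyopathy
8993	T	G	MT-ATP6 NARP/Leigh
8993	T	C	MT-ATP6 NARP/Leigh
9176	T	C	MT-ATP6 Leigh
9185	T	C	MT-ATP6 Leigh
10158	T	C	MT-ND3 Leigh
10191	T	C	MT-ND3 Leigh
10197	G	A	MT-ND3 Leigh/dystonia
11777	C	A	MT-ND4 Leigh
11778	G	A	MT-ND4 LHON
13513	G	A	MT-ND5 MELAS/Leigh
13514	A	G	MT-ND5 MELAS/Leigh
14459	G	A	MT-ND6 LHON/dystonia
14484	T	C	MT-ND6 LHON
14487	T	C	MT-ND6 Leigh/dystonia
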