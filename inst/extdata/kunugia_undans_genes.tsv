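# Kunugia undans (KU) mitogenome organization: published coordinates with
# the parenthesized gap column as printed_gap. 15,570 bp, circular; carries
# a duplicated trnR (copies at 6084-6147 and 6175-6241), the arrangement
# peculiarity of this genus.
genome_id	gene	type	strand	start	end	copy_index	printed_gap
KU	trnM	tRNA	J	1	68	1
KU	trnI	tRNA	J	72	135	1	3
KU	trnQ	tRNA	N	136	205	1	0
KU	ND2	PCG	J	263	1276	1	57
KU	trnW	tRNA	J	1275	1344	1	-2
KU	trnC	tRNA	N	1337	1402	1	-8
KU	trnY	tRNA	N	1412	1479	1	9
KU	COI	PCG	J	1500	3057	1	20
KU	trnL2	tRNA	J	3058	3125	1	0
KU	COII	PCG	J	3125	3806	1	-1
KU	trnK	tRNA	J	3807	3877	1	0
KU	trnD	tRNA	J	3879	3947	1	1
KU	ATP8	PCG	J	3948	4109	1	0
KU	ATP6	PCG	J	4103	4780	1	-7
KU	COIII	PCG	J	4787	5575	1	6
KU	trnG	tRNA	J	5578	5644	1	2
KU	ND3	PCG	J	5645	5998	1	0
KU	trnA	tRNA	J	6003	6070	1	4
KU	trnR	tRNA	J	6084	6147	1	13
KU	trnR	tRNA	J	6175	6241	2	27
KU	trnN	tRNA	J	6242	6308	1	0
KU	trnS1	tRNA	J	6308	6375	1	-1
KU	trnE	tRNA	J	6376	6440	1	0
KU	trnF	tRNA	N	6471	6537	1	30
KU	ND5	PCG	N	6538	8275	1	0
KU	trnH	tRNA	N	8276	8343	1	0
KU	ND4	PCG	N	8348	9682	1	4
KU	ND4L	PCG	N	9688	9981	1	5
KU	trnT	tRNA	J	9986	10050	1	4
KU	trnP	tRNA	N	10051	10115	1	0
KU	ND6	PCG	J	10124	10654	1	8
KU	CytB	PCG	J	10662	11807	1	7
KU	trnS2	tRNA	J	11809	11875	1	1
KU	ND1	PCG	N	11869	12825	1	-7
KU	trnL1	tRNA	N	12827	12892	1	1
KU	rrnL	rRNA	N	12893	14406	1	0
KU	trnV	tRNA	N	14407	14471	1	0
KU	rrnS	rRNA	N	14472	15253	1	0
KU	control_region	control_region	J	15254	15570	1
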