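name	from	to	strand	type
tRNA-Phe	1	68	H	tRNA
12S	69	1016	H	rRNA
tRNA-Val(tac)	1017	1088	H	tRNA
16S	1140	2779	H	rRNA
tRNA-Leu2(taa)	2788	2862	H	tRNA
ND1	2863	3837	H	PCG
tRNA-Ile(gat)	3842	3911	H	tRNA
tRNA-Gln(ttg)	3911	3981	L	tRNA
tRNA-Met(cat)	3981	4049	H	tRNA
ND2	4050	5096	H	PCG
tRNA-Trp(tca)	5097	5167	H	tRNA
tRNA-Ala(tgc)	5170	5238	L	tRNA
tRNA-Asn(gtt)	5240	5312	L	tRNA
OL	5317	5347	H	origin
tRNA-Cys(gca)	5348	5412	L	tRNA
tRNA-Tyr(gta)	5413	5483	L	tRNA
COI	5485	7038	H	PCG
tRNA-Ser2(tga)	7039	7109	L	tRNA
tRNA-Asp(gtc)	7113	7184	H	tRNA
COII	7189	7879	H	PCG
tRNA-Lys(ttt)	7880	7955	H	tRNA
ATP8	7957	8121	H	PCG
ATP6	8115	8800	H	PCG
COIII	8918	9570	H	PCG
tRNA-Gly(tcc)	9585	9656	H	tRNA
NAD3	9657	10007	H	PCG
tRNA-Arg(tcg)	10006	10074	H	tRNA
NAD4L	10075	10371	H	PCG
NAD4	10365	11745	H	PCG
tRNA-His(gtg)	11746	11814	H	tRNA
tRNA-Ser 1(gct)	11815	11882	H	tRNA
tRNA-Leu1(tag)	11886	11958	H	tRNA
NAD5	11959	13797	H	PCG
NAD6	13794	14318	L	PCG
tRNA-Glu(ttc)	14316	14384	L	tRNA
CYTB	14390	15530	H	PCG
tRNA-Thr(tgt)	15531	15603	H	tRNA
tRNA-Pro(tgg)	15605	15674	L	tRNA
OH	16170	16500	H	origin
D-loop	15675	16684	H	control
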