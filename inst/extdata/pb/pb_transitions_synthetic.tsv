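# SYNTHETIC protein-block transition weights (16 x 16, row = preceding
# block, column = following block). Constructed deterministically from
# the bundled prototypes: weight = exp(-RMSDA/30) over the 6 dihedrals
# shared by overlapping windows, zeroed when RMSDA > 80 deg. A stand-in
# for the published PB transition statistics, which are not redistributed
# here; the algorithms only require a weighted 16 x 16 table.
pb	a	b	c	d	e	f	g	h	i	j	k	l	m	n	o	p
a	0	0.096	0.5177	0.1664	0.1905	0.2318	0.155	0	0	0	0.0763	0	0	0	0	0
b	0.0746	0	0.0915	0.1221	0.1132	0.1234	0.1444	0	0	0	0	0.0751	0	0	0	0
c	0	0.1144	0.2135	0.5092	0.5686	0.6109	0.0967	0.0825	0	0.0768	0.091	0	0	0	0	0
d	0	0.1049	0.1276	0.8104	0.7852	0.5905	0	0.079	0	0.0821	0.0854	0	0	0	0	0
e	0	0	0	0.0923	0.1037	0.1219	0	0.6879	0	0	0	0	0	0	0	0
f	0	0.5051	0	0.0939	0.107	0.0973	0	0	0.1089	0	0.67	0.0868	0	0	0	0
g	0	0	0.0953	0	0	0	0.0805	0.1859	0	0	0	0	0	0	0.0859	0
h	0	0.0909	0	0	0	0	0	0	0.7669	0.1169	0.141	0	0	0	0	0
i	0.3421	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
j	0	0	0	0	0	0	0	0	0	0	0	0.0748	0	0	0	0
k	0	0.1054	0	0	0	0	0.0804	0	0	0	0.0917	0.9137	0.0849	0.0903	0	0
l	0	0	0	0	0	0	0.1931	0	0	0	0	0.0954	0.7145	0.7209	0.1249	0.1352
m	0	0	0	0	0	0	0.1452	0	0	0	0	0.0869	0.9486	0.7506	0.1203	0.1306
n	0	0	0	0	0	0	0.0837	0	0	0	0	0	0.1274	0.0978	0.8594	0
o	0	0	0	0	0	0	0.0756	0	0	0	0	0	0.1	0.108	0	0.7541
p	0.5445	0	0.0838	0	0	0	0.1267	0	0	0	0	0	0	0	0	0
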