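chrom	length	subgenome	centromere	homoeolog_group
A01	34500000	A	15200000	1
A02	31200000	A	13700000	2
A03	36800000	A	14100000	3
A04	23300000	A	10900000	4
A05	27800000	A	12600000	5
A06	28500000	A	14800000	6
A07	27300000	A	12200000	7
A08	21100000	A	10400000	8
A09	42200000	A	18600000	9
A10	20800000	A	9300000	9
C01	44900000	C	21500000	1
C02	50800000	C	24400000	2
C03	60400000	C	26700000	3
C04	56200000	C	25900000	4
C05	47100000	C	22300000	5
C06	42400000	C	20800000	6
C07	46800000	C	21100000	7
C08	42600000	C	19900000	8
C09	43500000	C	20600000	9
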