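chr1	0	122000000	p11	gneg
chr1	122000000	125000000	p11.1	acen
chr1	125000000	128000000	q11	acen
chr1	128000000	249250621	q11.2	gneg
chr2	0	90300000	p11	gneg
chr2	90300000	93300000	p11.1	acen
chr2	93300000	96300000	q11	acen
chr2	96300000	243199373	q11.2	gneg
chr3	0	88000000	p11	gneg
chr3	88000000	91000000	p11.1	acen
chr3	91000000	94000000	q11	acen
chr3	94000000	198022430	q11.2	gneg
chr4	0	47400000	p11	gneg
chr4	47400000	50400000	p11.1	acen
chr4	50400000	53400000	q11	acen
chr4	53400000	191154276	q11.2	gneg
chr5	0	45400000	p11	gneg
chr5	45400000	48400000	p11.1	acen
chr5	48400000	51400000	q11	acen
chr5	51400000	180915260	q11.2	gneg
chr6	0	58000000	p11	gneg
chr6	58000000	61000000	p11.1	acen
chr6	61000000	64000000	q11	acen
chr6	64000000	171115067	q11.2	gneg
chr7	0	56900000	p11	gneg
chr7	56900000	59900000	p11.1	acen
chr7	59900000	62900000	q11	acen
chr7	62900000	159138663	q11.2	gneg
chr8	0	42600000	p11	gneg
chr8	42600000	45600000	p11.1	acen
chr8	45600000	48600000	q11	acen
chr8	48600000	146364022	q11.2	gneg
chr9	0	46000000	p11	gneg
chr9	46000000	49000000	p11.1	acen
chr9	49000000	52000000	q11	acen
chr9	52000000	141213431	q11.2	gneg
chr10	0	37200000	p11	gneg
chr10	37200000	40200000	p11.1	acen
chr10	40200000	43200000	q11	acen
chr10	43200000	135534747	q11.2	gneg
chr11	0	50700000	p11	gneg
chr11	50700000	53700000	p11.1	acen
chr11	53700000	56700000	q11	acen
chr11	56700000	135006516	q11.2	gneg
chr12	0	32800000	p11	gneg
chr12	32800000	35800000	p11.1	acen
chr12	35800000	38800000	q11	acen
chr12	38800000	133851895	q11.2	gneg
chr13	0	14900000	p11	gneg
chr13	14900000	17900000	p11.1	acen
chr13	17900000	20900000	q11	acen
chr13	20900000	115169878	q11.2	gneg
chr14	0	14600000	p11	gneg
chr14	14600000	17600000	p11.1	acen
chr14	17600000	20600000	q11	acen
chr14	20600000	107349540	q11.2	gneg
chr15	0	16000000	p11	gneg
chr15	16000000	19000000	p11.1	acen
chr15	19000000	22000000	q11	acen
chr15	22000000	102531392	q11.2	gneg
chr16	0	33600000	p11	gneg
chr16	33600000	36600000	p11.1	acen
chr16	36600000	39600000	q11	acen
chr16	39600000	90354753	q11.2	gneg
chr17	0	21000000	p11	gneg
chr17	21000000	24000000	p11.1	acen
chr17	24000000	27000000	q11	acen
chr17	27000000	81195210	q11.2	gneg
chr18	0	14200000	p11	gneg
chr18	14200000	17200000	p11.1	acen
chr18	17200000	20200000	q11	acen
chr18	20200000	78077248	q11.2	gneg
chr19	0	23500000	p11	gneg
chr19	23500000	26500000	p11.1	acen
chr19	26500000	29500000	q11	acen
chr19	29500000	59128983	q11.2	gneg
chr20	0	24500000	p11	gneg
chr20	24500000	27500000	p11.1	acen
chr20	27500000	30500000	q11	acen
chr20	30500000	63025520	q11.2	gneg
chr21	0	10200000	p11	gneg
chr21	10200000	13200000	p11.1	acen
chr21	13200000	16200000	q11	acen
chr21	16200000	48129895	q11.2	gneg
chr22	0	11700000	p11	gneg
chr22	11700000	14700000	p11.1	acen
chr22	14700000	17700000	q11	acen
chr22	17700000	51304566	q11.2	gneg
chrX	0	57600000	p11	gneg
chrX	57600000	60600000	p11.1	acen
chrX	60600000	63600000	q11	acen
chrX	63600000	155270560	q11.2	gneg
chrY	0	9500000	p11	gneg
chrY	9500000	12500000	p11.1	acen
chrY	12500000	15500000	q11	acen
chrY	15500000	59373566	q11.2	gneg
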