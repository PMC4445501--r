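Read count	Percentage	CDR3 nucleotide sequence	CDR3 amino acid sequence	V segments	D segments	J segments	Last V nucleotide position	First D nucleotide position	Last D nucleotide position	First J nucleotide position	VD insertions	DJ insertions	Total insertions
21	0.244186046511628	TGTACCCCCTGCGTACCGCTGGCATAAGGCCAGGGGAGTCTAGGCTTT	CTPCVPLA*GQGSLGF	TRBV6-1	TRBD2	TRBJ2-3	11	13	25	34	1	8	9
10	0.116279069767442	TGTGTAACTCCGGAACACGAGTCGCCTAGAAGAGGGAGTCTAGGCTTT	CVTPEHESPRRGSLGF	TRBV2-1	TRBD1	TRBJ2-3	14	19	28	34	4	5	9
4	0.0465116279069767	TGTGTAGAATGCAGTCGCCTAGACACGCACGCCTCCCGTTT	CVECSRLDTHASR~	TRBV3-1	TRBD1	TRBJ1-1	9	12	22	27	2	4	6
3	0.0348837209302326	TGTACCCCCTGCACGGTACCGCTGGCATTCATGACCTTT	CTPCTVPLAFMTF	TRBV6-1	TRBD2	TRBJ1-3	14	15	27	28	0	0	0
3	0.0348837209302326	TGTATCCCTACAGTACCGCTGGCATACTCGTGCATCACTTT	CIPTVPLAYSCIT~	TRBV9-1	TRBD2	TRBJ2-1	11	12	25	26	0	0	0
3	0.0348837209302326	TGTCATATCTCGTGGGTACCGCTGGCATAAGCCTCAAGCTTT	CHISWVPLA*ASSF	TRBV5-1	TRBD2	TRBJ2-2	13	14	27	28	0	0	0
3	0.0348837209302326	TGTTATATGCCGAACACGTACCGCTGGCATAACACGCCTCCCGTTT	CYMPNTYRWHNTPPV~	TRBV10-1	TRBD2	TRBJ1-1	13	18	30	32	4	1	5
2	0.0232558139534884	TGTACCCCCTGCACGAGTCGCCTAGAAACGGAGTCTAGGCTTT	CTPCTSRLETESRL~	TRBV6-1	TRBD1	TRBJ2-3	14	15	26	28	0	1	1
2	0.0232558139534884	TGTATCCCTACACTGAGGTACCGCTGAGTTGCCGTCTTCTTT	CIPTLRYR*VAVFF	TRBV9-1	TRBD2	TRBJ1-2	14	15	25	28	0	2	2
2	0.0232558139534884	TGTATCCCTACACTGCAGGTACCGCTGGCATCAACTTCATGACCTTT	CIPTLQVPLASTS*P~	TRBV9-1	TRBD2	TRBJ1-3	14	17	30	32	2	1	3
2	0.0232558139534884	TGTATCCCTACACTGCCGCTGGCATAGTTGCCGTCTTCTTT	CIPTLPLA*LPSS~	TRBV9-1	TRBD2	TRBJ1-2	14	15	25	27	0	1	1
2	0.0232558139534884	TGTATCCCTACACTGTAGTCGCCTAGCGCAGTCTAGGCTTT	CIPTL*SPSAV*A~	TRBV9-1	TRBD1	TRBJ2-3	14	17	25	29	2	3	5
2	0.0232558139534884	TGTCATATCTCGTGAGGTGGGTACCGCTGGCATCGGAGTCTAGGCTTT	CHIS*GGYRWHRSLGF	TRBV5-1	TRBD2	TRBJ2-3	14	19	32	33	4	0	4
1	0.0116279069767442	TGTAAAACTCCACTCGGAGTCGCCTAGAAATGAGTCTAGGCTTT	CKTPLGVA*K*V*A~	TRBV1-1	TRBD1	TRBJ2-3	11	17	28	31	5	2	7
1	0.0116279069767442	TGTAAAACTCCATGGTAGTCGCCTAGTCGTGCATCACTTT	CKTPW*SPSRASL~	TRBV1-1	TRBD1	TRBJ2-1	13	16	25	26	2	0	2
1	0.0116279069767442	TGTAAAACTTTTTAAGGTACCGCTGGCATAAAAGCCTCAAGCTTT	CKTF*GTAGIKASSF	TRBV1-1	TRBD2	TRBJ2-2	8	15	29	31	6	1	7
1	0.0116279069767442	TGTACCCCCTGCACGAGGTACCGCTGGCATCAAGCCTCAAGCTTT	CTPCTRYRWHQASSF	TRBV6-1	TRBD2	TRBJ2-2	14	15	28	31	0	2	2
1	0.0116279069767442	TGTACTCGGCCTTTTCGCCTAGAAATCCTCGTGCATCACTTT	CTRPFRLEILVHHF	TRBV4-1	TRBD1	TRBJ2-1	13	15	23	27	1	3	4
1	0.0116279069767442	TGTATCCCTACACCCTAGTCGCCTAGAACGCCTCCCGTTT	CIPTP*SPRTPPV~	TRBV9-1	TRBD1	TRBJ1-1	12	16	26	27	3	0	3
1	0.0116279069767442	TGTATCCCTACACTGTACCGCTGGCATAGGAGTCTAGGCTTT	CIPTLYRWHRSLGF	TRBV9-1	TRBD2	TRBJ2-3	14	15	27	28	0	0	0
1	0.0116279069767442	TGTATTAGGATATTCAGGTACCGCTGGCACCGTCTTCTTT	CIRIFRYRWHRLL~	TRBV8-1	TRBD2	TRBJ1-2	14	15	27	29	0	1	1
1	0.0116279069767442	TGTCATATCTCCGTACCGCTGGCATAACTTCATGACCTTT	CHISVPLA*LHDL~	TRBV5-1	TRBD2	TRBJ1-3	10	12	24	25	1	0	1
1	0.0116279069767442	TGTCATATCTCGTAACAGGAGGTACCGCTGGCATAGTGCCGTCTTCTTT	CHIS*QEVPLA*CRLL~	TRBV5-1	TRBD2	TRBJ1-2	12	19	34	36	6	1	7
1	0.0116279069767442	TGTCATATCTCGTGAACCGCTGGCTATTGCCGTCTTCTTT	CHIS*TAGYCRLL~	TRBV5-1	TRBD2	TRBJ1-2	14	15	22	26	0	3	3
1	0.0116279069767442	TGTCATATCTCGTGACAGGTACCGCTGGCATACAAAAGCCTCAAGCTTT	CHIS*QVPLAYKSLKL~	TRBV5-1	TRBD2	TRBJ2-2	14	16	31	34	1	2	3
1	0.0116279069767442	TGTCATATCTCGTGATCCCGCTGGCATCGCTCAAGCTTT	CHIS*SRWHRSSF	TRBV5-1	TRBD2	TRBJ2-2	14	17	26	29	2	2	4
1	0.0116279069767442	TGTCATATCTCGTGTTTAGTGGTCGCCTAGAATAAAAGCCTCAAGCTTT	CHISCLVVA*NKSLKL~	TRBV5-1	TRBD1	TRBJ2-2	13	21	31	34	7	2	9
1	0.0116279069767442	TGTGTAACTCCGGAATGTACCGCTGGCATTTCATGACCTTT	CVTPECTAGIS*P~	TRBV2-1	TRBD2	TRBJ1-3	14	16	28	29	1	0	1
1	0.0116279069767442	TGTGTAACTCCGGAGTCGCCTAGAATGCGCCTCCCGTTT	CVTPESPRMRLPF	TRBV2-1	TRBD1	TRBJ1-1	12	13	24	27	0	2	2
1	0.0116279069767442	TGTGTAGAAAGTCGCCTAGAACCTTCATGACCTTT	CVESRLEPS*P~	TRBV3-1	TRBD1	TRBJ1-3	8	9	20	24	0	3	3
1	0.0116279069767442	TGTGTAGAATCTTACCGCTGGCATCGGAGTCTAGGCTTT	CVESYRWHRSLGF	TRBV3-1	TRBD2	TRBJ2-3	12	13	23	24	0	0	0
1	0.0116279069767442	TGTGTAGAATCTTGAGTCGCCTTCGTGCATCACTTT	CVES*VAFVHHF	TRBV3-1	TRBD1	TRBJ2-1	12	14	21	22	1	0	1
1	0.0116279069767442	TGTGTAGAATCTTGCCCGAGTCGCCTAGAACTACGAAAAGCCTCAAGCTTT	CVESCPSRLELRKASSF	TRBV3-1	TRBD1	TRBJ2-2	14	18	29	36	3	6	9
1	0.0116279069767442	TGTGTAGAATCTTGGTACCGCTGGCATACGGAGTCTAGGCTTT	CVESWYRWHTESRL~	TRBV3-1	TRBD2	TRBJ2-3	12	13	27	28	0	0	0
1	0.0116279069767442	TGTGTTCTAATAAACTCGTACCGCTGGCATAAACTTCATGACCTTT	CVLINSYRWHKLHDL~	TRBV11-1	TRBD2	TRBJ1-3	14	18	30	31	3	0	3
1	0.0116279069767442	TGTTATATGAAGTCGCCTAGAATAAAGCCTCAAGCTTT	CYMKSPRIKPQA~	TRBV10-1	TRBD1	TRBJ2-2	8	10	21	23	1	1	2
1	0.0116279069767442	TGTTATATGCCGAACCCGCTGGCAGAAGCCTCAAGCTTT	CYMPNPLAEASSF	TRBV10-1	TRBD2	TRBJ2-2	14	15	23	25	0	1	1
1	0.0116279069767442	TGTTATATGCCGAACCTGGTACCGCTGGCATACACGGAGTCTAGGCTTT	CYMPNLVPLAYTESRL~	TRBV10-1	TRBD2	TRBJ2-3	14	17	31	34	2	2	4
1	0.0116279069767442	TGTTATATGCCGCGCCTAGAACTCGTGCATCACTTT	CYMPRLELVHHF	TRBV10-1	TRBD1	TRBJ2-1	11	12	20	21	0	0	0
1	0.0116279069767442	TGTTATATGCCGCGTCTCAGGTACCGCTGGCATTCGTTGACACTTCATGACCTTT	CYMPRLRYRWHSLTLHDL~	TRBV10-1	TRBD2	TRBJ1-3	11	19	32	41	7	8	15
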