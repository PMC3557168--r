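genotype	read_length_bp	n_reads	total_mbp	n_reads_mapped	mapped_mbp
CDC_Bethune	50	34290788	1715	31817354	1591
Macbeth	50	32815888	1641	30297145	1515
SP2047	50	35570612	1779	32667382	1633
UGG5-5	50	32046570	1602	29139577	1457
Double_Low	75	56669792	4250	47272267	3545
Crepitam_Tabor	75	57974144	4348	46740722	3506
G-1186/94	100	57867644	5787	45245067	4525
Atlas	100	56900660	5690	45599045	4560
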