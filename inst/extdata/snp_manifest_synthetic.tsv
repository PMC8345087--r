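rsid	risk_allele	protective_allele	context	snp_offset	source
rs10514231	T	C	GTGCTTCTGTGATATGTAAACTAGCTCAAATGGTGGTGTGATATGAAGTCAAGCTTGAGTC	30	GWAS catalog
rs2089222	A	G	TTAGAGCAAGGAAGTGTCTTAACAGTGCTCAGAGACGCGTGTGTGATTACATCATACTAGC	30	GWAS catalog
rsSIM0001	T	C	GCGGGTTGTAAATGTTGACCGGCCCTCAGATGAGTAGGGCTCCCAGGACAGCTCAGCGGCA	30	GWAS catalog
rsSIM0002	T	A	ATGGGGACGCTCCTGGAACTCACAGCTCGTTGAATAACAGTAGCAATACTTTCATCGAGTT	30	GWAS catalog
rsSIM0003	A	T	GTGCAGTGAGAGGGATGTTAGGAATGGGTTATGATTATCTCGATTTCGGCCGCCGAGTGCC	30	GWAS catalog
rsSIM0004	C	A	AGGGCCAATACTAAAACCGGATTAGGAAAGCTAGGTCAATGCCATTGTTTCCTTGGTTGTG	30	publication
rsSIM0005	A	C	CGACCACCTTGGATACACCCTCAGACCCGTATCTTGTCGCCAAATTCGACCTATACGAGCG	30	publication
rsSIM0006	G	T	TCTGGGCTGTAGCGCCTTAGACGAAGATAAGAAGAGAGACAGTACAGTCGGGCAGGTATAA	30	publication
rsSIM0007	T	G	AAAGTGAGCCGCTCCTAAGGGGCCTAGGCTTATATTCTGTTTAGGGTACAATTGTGACTGA	30	publication
rsSIM0008	T	C	TTGATACAGGTCATCGGTCCATCGGCTGCTTAATGGCTAAAGAGCCTCAGCCGAGTGCTCT	30	publication
rsSIM0009	G	C	TCAAAATAATGGTCGCAATAGAAGGAATAGGGAAAGTTATCCCTGGCCTTTTGGACGCGAA	30	publication
rsSIM0010	G	C	AAACACGTGGCGACGGGCCGCCCGATCGCAGCCCGGGGGGGGACGAAAACCTGGAGCGGTC	30	publication
rsSIM0011	G	A	TGTGGCGAGCGTCTCTTCTTCTTGGACTGGGACTACAAGGGCTAACGATCCCCACCACAGG	30	publication
rsSIM0012	G	C	GACAGGTCGCCAAGTTTAGGCGGCCACTTCGATCGATCTACTCGATGCTCTATTAGTACGT	30	publication
rsSIM0013	C	A	TCGTTTGGCCAGGAGCAACGGCAAATAGCCCCGCACGGCTACCCGAATACATGCTCCCTCT	30	publication
rsSIM0014	T	G	TAATCTACGACAGGGAGTCGCCAGACTAAATTCACATTGTCCTAGAACTAGGAACATACTA	30	publication
rsSIM0015	C	G	CATACGCCTTTGTGTGTTCCGCGTAGAGAACGCACACGTCGTTTGTGGAGGGACGCAGCTA	30	publication
rsSIM0016	A	C	CAGATGGCCCGGTAATTCGCGCCGCTCTGAAAGAAACCACAAGTTTCTGCCAACGTATTCC	30	publication
rsSIM0017	C	G	AGCCGCCGAGTGTTGTCCATGACAGCCATTCGGCCGATGGCCGGTATCTGTTTAGATAGTG	30	publication
rsSIM0018	C	G	GCTAAGCTGGTCCCCTGATTGCAAAGCTGGCGAAGGGCAATGCCTTGTCTTCTCGGAATAA	30	publication
rsSIM0019	C	T	AGCAAAGACACCTATTAGGTGAGAGTCATACGTTTTTGTCTCTGCAGTGATCCTGGTGTTC	30	publication
rsSIM0020	A	G	GATGATTGCCGCACCTTCAAGCGACGGTGTATCGAGTCCTCTTCCCGGGCGTCACGAGGAG	30	publication
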