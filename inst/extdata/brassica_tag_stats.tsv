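species	raw_total	raw_distinct	clean_total	clean_distinct	gene_total	gene_distinct	unambiguous_total	unambiguous_distinct	tag_mapped_genes	unambiguous_tag_mapped_genes	genome_total	genome_distinct	unknown_total	unknown_distinct	ref_genes
Br	6178564	293575	6018254	133499	1964909	44267	1679848	39414	19023	16574	2437918	44076	1615427	45156	41174
Bg	5881618	214427	5772449	106552	1990442	30413	1635594	26114	16687	13867	1147106	15159	2634901	60980	41174
Bo	6059222	243895	5930726	116771	1747843	36220	1475050	31933	18547	15970	2105332	30703	2077551	49848	41174
Bn	5964594	269285	5823113	128967	2253347	45358	1924944	40561	19955	17448	2164464	40689	1405302	42920	41174
Bj	6076830	400134	5858527	181965	1857572	56289	1531974	49892	21995	19424	2047451	50304	1953504	75372	41174
Bc	5795234	278768	5657697	142281	1915305	40425	1594991	35285	19436	16645	1462061	29547	2280331	72309	41174
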