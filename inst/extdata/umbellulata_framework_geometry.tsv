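chrom	n_markers	map_size_cM
1U	81	66.47
2U	446	131.19
3U	391	110.64
4U	523	149.32
5U	451	181.09
6U	526	133.25
7U	591	176.82
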