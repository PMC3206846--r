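taxon	Hymeniacidon_heliophila	Haliclona_tubifera	Didemnum_sp	seawater
Alphaproteobacteria	85	11	7	66
Gammaproteobacteria	27	24	12	30
Cyanobacteria	11	4	10	7
other	12	6	16	32
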