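# Genetic-map (cM) and pseudochromosome (1-Mbp bin) coordinates of the
# Tyr-FISH-mapped onion markers. Values flagged "printed" are stated in the
# published study; values flagged "interpolated" are monotone
# reconstructions that reproduce only the stated marker ORDER (the study
# prints orders in its map-alignment figures, not every coordinate).
# Chromosome 6 cM values are in the as-published linkage-group orientation
# (which the physical map shows to be upended); Unigene7941's genetic rank
# comes from the figure order. mlh1 is absent from the genetic map
# (genetic_cM NA) and its pseudochromosome bin is placed concordantly
# between its physical neighbours. Pseudochromosome bins ascend from the
# short-arm-aligned end (chr2 total 444 Mbp, chr6 total 315 Mbp).
chromosome	marker_id	genetic_cM	cM_source	pseudo_mbp	mbp_source
2	Unigene28076	5.9	printed	6	printed
2	Unigene23526	9.0	printed	17	printed
2	CL5148.Contig1	11.0	interpolated	30	interpolated
2	Unigene572	13.0	interpolated	36	interpolated
2	Unigene10061	14.7	printed	41	printed
2	CL4449.Contig1	20.0	interpolated	60	interpolated
2	Unigene25645	26.0	interpolated	90	interpolated
2	Unigene27326	32.0	interpolated	120	interpolated
2	Unigene28713	45.0	interpolated	180	interpolated
2	Unigene5305	58.0	interpolated	240	interpolated
2	mlh1	NA	absent	250	interpolated
2	Unigene10683	70.0	interpolated	260	interpolated
2	Unigene23418	80.0	interpolated	300	interpolated
6	Unigene8201	10.9	printed	280	interpolated
6	Unigene28149	13.5	printed	250	interpolated
6	CL39.Contig3	25.0	interpolated	200	interpolated
6	Unigene22659	35.0	interpolated	150	interpolated
6	Unigene10558	45.0	interpolated	170	interpolated
6	Unigene49	55.0	interpolated	130	interpolated
6	CL4877.Contig2	65.0	interpolated	110	interpolated
6	Unigene13863	75.0	interpolated	90	interpolated
6	Unigene7941	90.0	interpolated	60	interpolated
6	Unigene13813	101.5	printed	30	interpolated
6	CL6133.Contig1	106.7	printed	10	interpolated
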