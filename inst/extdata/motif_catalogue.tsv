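motif_id	name	pattern	search_both_strands
chi_like	Chi-like element	GCTGGTGG	TRUE
translin_1	Translin target site (ATGCAG class)	ATGCAG	TRUE
translin_2	Translin target site (GCCCWSSW class)	GCCCWSSW	TRUE
ig_switch_1	Immunoglobulin class-switch repeat unit GAGCT	GAGCT	TRUE
ig_switch_2	Immunoglobulin class-switch repeat unit GGGGT	GGGGT	TRUE
rss_heptamer	V(D)J recombination signal heptamer	CACAGTG	TRUE
rss_nonamer	V(D)J recombination signal nonamer	ACAAAAACC	TRUE
topo2_consensus	Vertebrate topoisomerase II cleavage consensus	RNYNNCNNGYNGKTNYNY	TRUE
topo1_site	Topoisomerase I cleavage preference	CTT	TRUE
del_hotspot	Deletion hotspot consensus	TGRRKM	TRUE
pol_pause	DNA polymerase arrest/pause site	GAGGAG	TRUE
a_tract	A-tract (bent DNA)	AAAAAA	TRUE
apr_tract	Alternating purine-pyrimidine tract	RYRYRYRYRYRY	TRUE
minisat_core	Minisatellite core consensus	GGGCAGGARG	TRUE
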