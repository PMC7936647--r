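##fileformat=VCFv4.2
##contig=<ID=chrA,length=10000>
##INFO=<ID=DPT,Number=1,Type=Integer,Description="Treated sample depth">
##INFO=<ID=DPC,Number=1,Type=Integer,Description="Control sample depth">
##INFO=<ID=ALTS,Number=1,Type=Integer,Description="Alt-supporting reads">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrA	2101	.	G	T	66.0	PASS	DPT=25;DPC=27;ALTS=9
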