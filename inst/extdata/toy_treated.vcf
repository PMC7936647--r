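##fileformat=VCFv4.2
##contig=<ID=chrA,length=10000>
##contig=<ID=chrB,length=10000>
##INFO=<ID=DPT,Number=1,Type=Integer,Description="Treated sample depth">
##INFO=<ID=DPC,Number=1,Type=Integer,Description="Control sample depth">
##INFO=<ID=ALTS,Number=1,Type=Integer,Description="Alt-supporting reads">
##INFO=<ID=AB,Number=1,Type=Float,Description="Allele balance">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrA	101	.	C	A	60.0	PASS	DPT=30;DPC=30;ALTS=10
chrA	201	.	G	T	55.0	PASS	DPT=28;DPC=25;ALTS=8
chrA	301	.	T	C	70.0	PASS	DPT=40;DPC=35;ALTS=12
chrA	401	.	A	G	45.0	PASS	DPT=22;DPC=21;ALTS=5
chrA	501	.	C	T	90.0	PASS	DPT=33;DPC=29;ALTS=15
chrA	601	.	G	C	40.0	PASS	DPT=20;DPC=20;ALTS=4
chrA	701	.	T	A	52.0	PASS	DPT=26;DPC=30;ALTS=9
chrA	801	.	C	G	48.0	PASS	DPT=31;DPC=27;ALTS=7
chrA	901	.	A	T	66.0	PASS	DPT=29;DPC=24;ALTS=11
chrA	1101	.	T	G	58.0	PASS	DPT=35;DPC=32;ALTS=13
chrA	1201	.	CA	TG	62.0	PASS	DPT=30;DPC=28;ALTS=14;AB=0.4667
chrA	1301	.	G	A	44.0	PASS	DPT=21;DPC=23;ALTS=6
chrA	1401	.	C	A	39.5	PASS	DPT=30;DPC=30;ALTS=10
chrA	1501	.	T	C	10.0	PASS	DPT=25;DPC=25;ALTS=8
chrA	1601	.	G	T	80.0	PASS	DPT=10;DPC=30;ALTS=5
chrA	1701	.	A	C	75.0	PASS	DPT=30;DPC=19;ALTS=9
chrA	1801	.	C	G	65.0	PASS	DPT=25;DPC=26;ALTS=3
chrA	1901	.	TG	AT	70.0	PASS	DPT=30;DPC=30;ALTS=4;AB=0.1000
chrB	1500	.	C	T	85.0	PASS	DPT=30;DPC=30;ALTS=10
chrA	2101	.	G	T	77.0	PASS	DPT=28;DPC=30;ALTS=12
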