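# Curated exon-overlapping IES candidates from the Tetrahymena thermophila
# SB210 MIC genome survey. conmac_pos: approximate browser coordinate of the
# site on the concatenated MAC reference. ttherm: host gene model number.
# evidence: e = expression (EST/microarray), a = protein domain annotation.
# reads: supporting one-end Sanger reads (L/R). junction: rendered MAC
# junction (lowercase flanks, uppercase retained microhomology, "/" = blunt
# join). exon: position of the host exon in the gene model. length_bp:
# determined IES length (NA = not determined); length_exact marks lengths
# established exactly (TRUE) vs approximate/lower-bound estimates (FALSE).
ies	conmac_pos	ttherm	evidence	reads	junction	exon	length_bp	length_exact
1	18231806	00142380	e,a	1L+1R	ttaTTAAtgg	3'	194	TRUE
2	41846824	00348490	e,a	1L+2R	ttaTTAAtta	5'	453	TRUE
3	62203355	00586680	e,a	2L+3R	tttTTAATTttt	Single	NA	NA
A	94944570	01101620	e	1L+1R	tacATAatc	Single	483	TRUE
B	15671490	00569290	e,a	1R	tcaTTAAatt	3'	337	TRUE
C	64246345	00617820	e	3L+3R	cccAAtgt	3'	1500	FALSE
D	24290765	00198180	e,a	1L+1R	atat/cctg	Mid	1200	FALSE
E	95586240	01119380	e	1L+1R	aaaGAttg	Mid	2000	FALSE
F	42109185	00359230	e,a	1L+3R	tccTtta	Jxn 3'	NA	NA
G	99551500	01259660	a	3L+1R	gtcAAata	5'	NA	NA
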