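# format_version: 1
identifier	weight	provenance
BRAF:p.Val600Glu	0.95	
TERT:c.1-124C>T	0.85	
TERT:c.1-146C>T	0.85	
RET:p.Met918Thr	0.95	
RET:p.Cys634Arg	0.90	
RET:deletion	0.85	
NRAS:p.Gln61Arg	0.50	
NRAS:p.Gln61Lys	0.50	
HRAS:p.Gln61Arg	0.50	
KRAS:p.Gln61Arg	0.50	
KRAS:p.Gly12Asp	0.50	
PAX8:PAX8-PPARG	0.55	
SLX4:pathogenic	0.30	
ATM:pathogenic	0.30	
GNAS:p.Arg201Cys	0.20	
ESR1:pathogenic	0.15	
TET2:pathogenic	0.15	
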