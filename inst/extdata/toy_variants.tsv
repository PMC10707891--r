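#chrom	pos	ref	alt	wt_alt	wt_total	mut_alt	mut_total
chr01	100	C	T	3	15	20	20
chr01	200	G	A	3	15	19	20
chr02	300	C	T	10	15	20	20
chr02	400	A	C	2	15	2	20
chr03	500	CA	C	8	15	10	20
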