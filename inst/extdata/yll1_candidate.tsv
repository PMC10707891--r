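#chrom	pos	ref	alt	wt_alt	wt_total	mut_alt	mut_total
chr01	2771134	C	T	2	16	29	29
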