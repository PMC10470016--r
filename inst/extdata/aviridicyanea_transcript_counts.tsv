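class	status	count
lncRNA	all	17193
mRNA	known	17730
mRNA	novel	8631
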