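class	status	up	down
lncRNA	all	8120	419
mRNA	known	8432	650
mRNA	novel	3926	255
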