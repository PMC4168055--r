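type	p1	p2	value
stack	AT	AT	-0.93
stack	AT	TA	-1.1
stack	AT	GC	-2.08
stack	AT	CG	-2.24
stack	AT	GT	-0.55
stack	AT	TG	-1.36
stack	TA	AT	-1.33
stack	TA	TA	-0.93
stack	TA	GC	-2.11
stack	TA	CG	-2.35
stack	TA	GT	-1
stack	TA	TG	-1.27
stack	GC	AT	-2.35
stack	GC	TA	-2.24
stack	GC	GC	-3.26
stack	GC	CG	-3.42
stack	GC	GT	-1.47
stack	GC	TG	-2.51
stack	CG	AT	-2.11
stack	CG	TA	-2.08
stack	CG	GC	-2.36
stack	CG	CG	-3.26
stack	CG	GT	-1.47
stack	CG	TG	-2.11
stack	GT	AT	-1.27
stack	GT	TA	-1.36
stack	GT	GC	-2.11
stack	GT	CG	-2.51
stack	GT	GT	-0.5
stack	GT	TG	1.29
stack	TG	AT	-1
stack	TG	TA	-0.55
stack	TG	GC	-1.47
stack	TG	CG	-1.47
stack	TG	GT	0.3
stack	TG	TG	-0.5
loop	hairpin_a		4.5
loop	hairpin_b		0.25
loop	bulge_a		3.3
loop	bulge_b		0.25
loop	internal_a		1.5
loop	internal_b		0.25
loop	multi_a		3.4
loop	multi_b		0.4
loop	multi_c		0.1
loop	max_internal		20
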