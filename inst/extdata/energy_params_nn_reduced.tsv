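# parameter_set: nn-reduced-1.0
# Reduced nearest-neighbor free-energy set (kcal/mol, 37 C): Watson-Crick
# stacks from published duplex nearest-neighbor values; G:U wobble stacks
# approximate; affine (open + per-nt) loop penalties; duplex initiation.
# Stack name XY-ZW: 5-prime pair X:Y stacked on 3-prime pair Z:W (top strand X,Z).
category	name	value
stack	AU-AU	-0.93
stack	AU-CG	-2.24
stack	AU-GC	-2.08
stack	AU-GU	-0.55
stack	AU-UA	-1.10
stack	AU-UG	-1.36
stack	CG-AU	-2.11
stack	CG-CG	-3.26
stack	CG-GC	-2.36
stack	CG-GU	-1.41
stack	CG-UA	-2.08
stack	CG-UG	-2.11
stack	GC-AU	-2.35
stack	GC-CG	-3.42
stack	GC-GC	-3.26
stack	GC-GU	-1.53
stack	GC-UA	-2.24
stack	GC-UG	-2.51
stack	GU-AU	-0.55
stack	GU-CG	-2.51
stack	GU-GC	-2.11
stack	GU-GU	-0.50
stack	GU-UA	-1.36
stack	GU-UG	1.29
stack	UA-AU	-1.33
stack	UA-CG	-2.35
stack	UA-GC	-2.11
stack	UA-GU	-1.00
stack	UA-UA	-0.93
stack	UA-UG	-0.55
stack	UG-AU	-1.00
stack	UG-CG	-1.53
stack	UG-GC	-1.41
stack	UG-GU	-0.57
stack	UG-UA	-0.55
stack	UG-UG	-0.50
scalar	duplex_init	4.09
scalar	bulge_open	3.80
scalar	bulge_ext	0.30
scalar	il_open	1.70
scalar	il_ext	0.30
scalar	hairpin_open	4.65
scalar	hairpin_ext	0.25
scalar	ml_open	3.40
scalar	ml_branch	0.40
scalar	ml_unpaired	0.05
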