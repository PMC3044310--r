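position	true_base	A	C	G	T
11	A	0.9618	0.0253	0.0019	0.0110
11	C	0.0020	0.9932	0.0008	0.0040
11	G	0.0012	0.0030	0.9760	0.0198
11	T	0.0009	0.0018	0.0013	0.9960
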