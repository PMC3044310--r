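position	true_base	A	C	G	T
11	A	0.9896	0.0063	0.0018	0.0023
11	C	0.0015	0.9960	0.0010	0.0015
11	G	0.0005	0.0017	0.9925	0.0053
11	T	0.0005	0.0019	0.0018	0.9958
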