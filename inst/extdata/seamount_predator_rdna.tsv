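feature_id	rDNA-pooled
Bacteriovoracales	2043
Bdellovibrionales	5148
Oligoflexales	245
Bdellovibrionota-other	19
Myxococcales	837
Haliangiales	267
Nannocystales	170
Polyangiales	812
VHS-B3-70	21
Polyangia-Blfdi19	135
bacteriap25	128
Other-prokaryotes	1077331
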