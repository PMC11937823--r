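feature_id	rRNA-pooled
Bacteriovoracales	3759
Bdellovibrionales	35860
Oligoflexales	142
Bdellovibrionota-other	27
Myxococcales	2701
Haliangiales	42
Nannocystales	770
Polyangiales	13384
VHS-B3-70	55
Polyangia-Blfdi19	426
bacteriap25	107
Other-prokaryotes	832322
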