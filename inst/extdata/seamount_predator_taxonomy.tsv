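feature_id	lineage
Bacteriovoracales	d__Bacteria;p__Bdellovibrionota;c__Bacteriovoracia;o__Bacteriovoracales
Bdellovibrionales	d__Bacteria;p__Bdellovibrionota;c__Bdellovibrionia;o__Bdellovibrionales
Oligoflexales	d__Bacteria;p__Bdellovibrionota;c__Oligoflexia;o__Oligoflexales
Bdellovibrionota-other	d__Bacteria;p__Bdellovibrionota
Myxococcales	d__Bacteria;p__Myxococcota;c__Myxococcia;o__Myxococcales
Haliangiales	d__Bacteria;p__Myxococcota;c__Polyangia;o__Haliangiales
Nannocystales	d__Bacteria;p__Myxococcota;c__Polyangia;o__Nannocystales
Polyangiales	d__Bacteria;p__Myxococcota;c__Polyangia;o__Polyangiales
VHS-B3-70	d__Bacteria;p__Myxococcota;c__VHS-B3-70
Polyangia-Blfdi19	d__Bacteria;p__Myxococcota;c__Polyangia;o__Polyangia-Blfdi19
bacteriap25	d__Bacteria;p__Myxococcota;c__bacteriap25
Other-prokaryotes	d__Bacteria
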