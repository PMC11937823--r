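feature_id	rDNA-pooled
Archaea	80069
Bacteria	1006483
Unknown	604
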