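feature_id	rRNA-pooled
Archaea	17041
Bacteria	872413
Unknown	141
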