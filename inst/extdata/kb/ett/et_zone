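# safe zone: part of the trachea, 3-7 cm above the carina
PartOf trachea
Above carina_1 3cm 7cm
SearchShoulder 0.0
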