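PartOf kidney_cnn
NotPartOf dense_bone
LeftOf spine 50 100
SameLevelAs kidney_right_init 30
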