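abdomen
dense_bone
spine
kidney_cnn
kidney_right_init
kidney_left_init
kidney_right
kidney_left
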