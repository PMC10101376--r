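trachea
carina_1
carina_2
carina_3
et_tube
et_tip
et_zone
et_tip_correct
et_path_correct
et_tube_correct
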