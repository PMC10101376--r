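# carina estimate 1: inferior end of the trachea air column
BottomOf trachea
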