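# dark air column; closing reconnects the band across the overlying tube
IntensityRange 0 250
MorphClose 3
FillHoles
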