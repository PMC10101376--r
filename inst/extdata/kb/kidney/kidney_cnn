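# initial kidney candidates; soft-tissue range on contrast-enhanced CT.
# A trained predictor hook can replace this threshold via ExternalPredictor.
IntensityRange 300 2000
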