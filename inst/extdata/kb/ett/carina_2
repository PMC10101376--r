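# carina estimate 2: an external detector (not_found when no hook is given)
ExternalPredictor carina_detector
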