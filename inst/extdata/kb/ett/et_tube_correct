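DecisionAnd et_tip_correct et_path_correct
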