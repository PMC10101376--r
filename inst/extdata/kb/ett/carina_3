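# the two carina estimates must correspond; otherwise report unreliable
ConsistentWith carina_1 carina_2 10
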