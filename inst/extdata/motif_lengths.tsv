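# TF -> motif length (bp)
USF1	12
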