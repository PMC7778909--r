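segment	kind	anchor_index	applies_before_anchor
TM5	bulge	46	TRUE
TM7	constriction	33	TRUE
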