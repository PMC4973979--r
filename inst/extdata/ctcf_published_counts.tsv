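quantity	numerator	denominator
position9_substitutions_inside_anchors	204	792
position9_substitutions_outside_anchors	83	539
substitutions_affecting_multiple_tfbs	2123	4782
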