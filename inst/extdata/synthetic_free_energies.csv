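label,g_neutral,g_anion,unit
mid_O2_synthetic,0.0,281.06,kcal
mid_O3_synthetic,0.0,281.88,kcal
red_O6_synthetic,0.0,282.84,kcal
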