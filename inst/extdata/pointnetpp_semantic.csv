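strategy,Precision,Recall,F1,IoU
FPS,85.38,84.62,84.96,75.77
RS,85.29,84.81,85.01,76.00
UVS,86.07,86.15,85.90,77.03
VFPS,85.55,84.95,85.08,75.91
3DEPS,85.64,86.05,85.74,76.80
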