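strategy,Precision,Recall,F1,IoU
FPS,92.03,90.50,91.22,84.85
RS,93.23,92.09,92.64,87.04
UVS,92.53,91.75,92.13,86.25
VFPS,91.98,92.10,92.04,86.11
3DEPS,92.67,92.56,92.60,86.93
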