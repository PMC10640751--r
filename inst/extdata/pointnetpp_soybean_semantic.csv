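strategy,Precision,Recall,F1,IoU
FPS,72.42,70.18,71.33,58.91
RS,73.82,69.85,70.31,42.63
UVS,73.11,73.27,72.98,60.44
VFPS,71.19,68.66,69.56,57.42
3DEPS,70.04,66.63,67.62,53.26
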