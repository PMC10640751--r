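strategy,Precision,Recall,F1,IoU,Cov,WCov,mPrec,mRec
FPS,79.77,81.44,79.62,67.24,63.46,70.37,69.58,58.41
RS,82.67,82.09,82.04,70.28,62.85,70.34,67.73,53.56
UVS,83.97,81.09,81.93,70.18,61.29,69.10,68.73,52.15
VFPS,84.33,81.03,82.08,70.66,62.20,69.88,67.90,51.73
3DEPS,83.33,82.48,82.34,70.24,64.01,71.92,71.45,54.62
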