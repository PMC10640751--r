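strategy,Precision,Recall,F1,IoU,Cov,WCov,mPrec,mRec
FPS,91.83,89.56,90.63,83.22,77.27,83.23,81.89,76.19
RS,93.38,91.87,92.60,86.66,79.38,86.25,85.43,75.97
UVS,93.66,92.35,92.99,87.21,79.72,86.44,84.83,75.17
VFPS,93.67,91.84,92.77,86.88,77.90,85.55,81.61,73.70
3DEPS,93.61,92.45,93.02,87.29,79.22,86.25,85.10,75.60
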