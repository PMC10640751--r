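strategy,Precision,Recall,F1,IoU,Cov,WCov,mPrec,mRec
FPS,90.03,89.38,89.68,81.90,79.63,85.50,84.30,78.18
RS,91.71,91.04,91.35,84.62,78.79,85.67,83.54,72.80
UVS,93.10,92.62,92.67,86.78,80.12,86.77,85.37,74.99
VFPS,92.26,92.14,92.18,85.99,78.21,85.67,85.05,72.27
3DEPS,92.24,91.86,92.04,85.74,79.03,85.92,84.37,73.48
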