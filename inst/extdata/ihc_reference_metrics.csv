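panel,marker,sens,sens_lo,sens_hi,spec,spec_lo,spec_hi,ppv,npv,auc
HSIL,p16,92.6,83.7,97.6,63.4,53.2,72.7,63.0,92.8,0.78
HSIL,Ki-67,91.2,81.8,96.7,80.2,71.1,87.5,75.6,93.1,0.86
HSIL,p16+Ki-67,88.2,78.1,94.8,87.1,79.0,93.0,82.2,91.7,0.88
HSIL,TOP2A,88.2,78.1,94.8,87.1,79.0,93.0,82.2,91.7,0.88
HSIL,RFC4,88.2,78.1,94.8,90.1,82.5,95.1,85.7,91.9,0.89
HSIL+,p16,95.3,90.2,98.3,63.4,53.2,72.7,76.9,91.4,0.79
HSIL+,Ki-67,93.0,87.2,96.8,80.2,71.1,87.5,85.7,90.0,0.87
HSIL+,p16+Ki-67,90.7,84.3,95.1,87.1,79.0,93.0,90.0,88.0,0.89
HSIL+,TOP2A,91.5,85.3,95.7,87.1,79.0,93.0,90.1,88.9,0.89
HSIL+,RFC4,91.5,85.3,95.7,90.1,82.5,95.1,92.2,89.2,0.91
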