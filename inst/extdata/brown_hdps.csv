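label,point,lower,upper,level,scale,se
HDPS-adjusted hazard ratio,1.61,0.997,2.59,0.95,log,
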