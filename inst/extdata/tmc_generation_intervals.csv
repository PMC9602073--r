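path,n,mean_years,se_years
LSS,187,7.45,0.42
LSD,957,7.31,0.16
LDS,183,6.94,0.26
LDD,827,6.46,0.12
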