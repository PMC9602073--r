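class,n,mean_mb,sd_mb,mean_snp,sd_snp
1-2 Mb,7236,1.35,0.26,28,17
2-4 Mb,1444,2.66,0.52,51,28
4-8 Mb,453,5.55,1.16,123,56
8-16 Mb,268,11.28,2.24,243,70
>16 Mb,111,23.71,7.21,465,157
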