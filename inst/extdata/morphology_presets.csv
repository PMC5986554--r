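condition,species,weight,length_median_nm,length_sdlog,height_mean_nm,height_sd_nm
alone_12h,protofibril,0.84,110,0.28,2.1,0.5
alone_12h,fibril,0.16,500,0.35,5.4,0.7
alone_24h,fibril,0.875,430,0.42,3.6,0.85
alone_24h,protofibril,0.125,110,0.28,2.1,0.5
dopc_24h,thin_fibril,0.66,420,0.45,2.6,0.75
dopc_24h,fibril,0.34,430,0.42,4.2,0.85
chol_12h,fibril,0.875,430,0.42,3.6,0.85
chol_12h,protofibril,0.125,110,0.28,2.1,0.5
chol_24h,fibril,0.88,430,0.42,3.6,0.85
chol_24h,protofibril,0.12,110,0.28,2.1,0.5
7keto_24h,protofibril,0.873,110,0.28,2.1,0.5
7keto_24h,fibril,0.127,500,0.35,5.4,0.7
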