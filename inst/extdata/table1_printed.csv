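sub_region,min_ha,max_ha,mean_ha,sd_ha,baseline_mean_ha,baseline_sd_ha
Open Coast,215,441,335,76,361,63
Western Strait,545,1139,905,168,978,115
Eastern Strait,90,326,175,74,154,38
Smith & Minor Island AR,38,129,80.2,32,71,8
Cypress Island AR,9.3,15,12.8,2,15,1
Cherry Point AR,2.3,30,14.2,10,16,3
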