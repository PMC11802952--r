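year,baseline,growth_effect,aging_effect,total_need,needed_additional
2020,343202,0,0,343202,0
2025,343202,11961,5016,360179,16977
2030,343202,23174,9651,376027,32825
2035,343202,33245,13036,389483,46281
2040,343202,42186,15373,400761,57559
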