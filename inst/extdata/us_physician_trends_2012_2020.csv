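year,all_raw,all_age_adjusted,pcp_raw,pcp_age_adjusted,pcp_excl_hospitalists,hospitalists
2012,725405,700732,262578,255170,225345,29825
2013,739104,714281,266356,258662,227478,31184
2014,759321,733255,270749,262659,230356,32303
2015,771975,744274,274413,265791,231826,33965
2016,780613,751891,276250,267261,231927,35334
2017,793341,762712,277961,268383,231763,36620
2018,808584,775054,281160,270649,233084,37565
2019,821972,786697,284750,273604,234725,38879
2020,836136,796609,288326,275809,236497,39312
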