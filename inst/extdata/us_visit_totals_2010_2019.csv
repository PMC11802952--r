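year,subspecialist_visits,pcp_visits,np_nurse_visits_adj,pa_visits_adj,total_primary_care_visits
2010,505895969,515747034,42479207,6170431,564396673
2011,529984676,526947489,40194433,7558394,574700315
2012,531677700,504298245,41322465,7734806,553355516
2013,553978450,516131217,60400799,9917592,586449607
2014,595127138,525353084,77739214,10904799,613997097
2015,567944679,523331162,67662232,12611214,603604609
2016,539428957,511380920,68012511,13481649,592875079
2017,569404966,511232575,67383029,14636611,593252216
2018,617890253,531459310,76762932,16510441,624732684
2019,613168936,512333887,75200612,18158650,605693149
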