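year,np_all,np_primary_care,np_percent,pa_all,pa_primary_care,pa_percent
2016,150155,49694,33.1,91107,25677,28.2
2017,167125,54554,32.6,97526,26463,27.1
2018,192602,61972,32.2,106507,28388,26.7
2019,210919,67158,31.8,113440,29650,26.1
2020,229742,73750,32.1,119859,32955,27.5
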