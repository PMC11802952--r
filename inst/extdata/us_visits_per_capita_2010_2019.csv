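year,subspecialist,pcp,np_nurse,pa,total_primary_care
2010,1.64,1.67,0.14,0.02,1.83
2011,1.70,1.69,0.13,0.02,1.85
2012,1.70,1.61,0.13,0.02,1.77
2013,1.75,1.63,0.19,0.03,1.86
2014,1.87,1.65,0.24,0.03,1.93
2015,1.77,1.63,0.21,0.04,1.88
2016,1.67,1.58,0.21,0.04,1.83
2017,1.75,1.57,0.21,0.05,1.83
2018,1.89,1.63,0.24,0.05,1.91
2019,1.87,1.56,0.23,0.06,1.85
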