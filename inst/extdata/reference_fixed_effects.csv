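model,network,term,estimate,se
P1a,proximity,age,-0.0112,0.0051
P1a,proximity,sex,0.2702,0.2529
P1a,proximity,age:sex,-0.0135,0.0067
P1a,grooming total,age,-0.0232,0.0035
P1a,grooming total,sex,1.0043,0.2027
P1a,grooming total,age:sex,-0.0173,0.0038
P1b,proximity,age,-0.0029,0.0013
P1b,proximity,sex,-0.0007,0.0670
P1b,proximity,age:sex,-0.0021,0.0018
P1b,grooming given,age,0.0022,0.0010
P1b,grooming given,sex,-0.0227,0.0607
P1b,grooming given,age:sex,-0.0027,0.0015
P1b,grooming received,age,-0.0042,0.0013
P1b,grooming received,sex,-0.0222,0.0575
P1b,grooming received,age:sex,0.0003,0.0016
P1b,grooming total,age,-0.0010,0.0010
P1b,grooming total,sex,-0.0147,0.0449
P1b,grooming total,age:sex,-0.0014,0.0012
P1c.1,proximity,age,0.0053,0.0090
P1c.1,proximity,sex,-0.3070,0.4550
P1c.1,proximity,age:sex,0.0017,0.0120
P1c.1,grooming given,age,0.0198,0.0091
P1c.1,grooming given,sex,-0.1326,0.4849
P1c.1,grooming given,age:sex,-0.0172,0.0126
P1c.1,grooming received,age,-0.0088,0.0092
P1c.1,grooming received,sex,-0.4860,0.3657
P1c.1,grooming received,age:sex,0.0108,0.0115
P1c.1,grooming total,age,0.0096,0.0072
P1c.1,grooming total,sex,-0.3061,0.3116
P1c.1,grooming total,age:sex,-0.0022,0.0092
P1c.2,proximity,age,0.0219,0.0097
P1c.2,proximity,sex,0.3355,0.4720
P1c.2,proximity,age:sex,-0.0168,0.0128
P1c.2,grooming given,age,0.0161,0.0100
P1c.2,grooming given,sex,-0.9799,0.5681
P1c.2,grooming given,age:sex,-0.0024,0.0143
P1c.2,grooming received,age,-0.0112,0.0114
P1c.2,grooming received,sex,-0.1466,0.4497
P1c.2,grooming received,age:sex,0.0021,0.0141
P1c.2,grooming total,age,0.0198,0.0079
P1c.2,grooming total,sex,-0.0312,0.3522
P1c.2,grooming total,age:sex,-0.0134,0.0101
P2a,proximity,age,-0.0211,0.0039
P2a,proximity,sex,-0.3603,0.1936
P2a,proximity,age:sex,0.0069,0.0050
P2a,grooming given,age,0.0455,0.0019
P2a,grooming given,sex,-0.2985,0.0893
P2a,grooming given,age:sex,-0.0199,0.0025
P2a,grooming received,age,0.0069,0.0020
P2a,grooming received,sex,-0.0613,0.0922
P2a,grooming received,age:sex,-0.0022,0.0025
P2a,grooming total,age,0.0341,0.0019
P2a,grooming total,sex,-0.0125,0.0863
P2a,grooming total,age:sex,-0.0235,0.0023
P2b.1,proximity,age,-0.0211,0.0036
P2b.1,proximity,sex,-0.2964,0.1831
P2b.1,proximity,age:sex,0.0047,0.0047
P2b.1,grooming total,age,0.0097,0.0022
P2b.1,grooming total,sex,-0.0195,0.1005
P2b.1,grooming total,age:sex,-0.0068,0.0028
P2b.2,proximity,age,0.0054,0.0042
P2b.2,proximity,sex,0.1166,0.2167
P2b.2,proximity,age:sex,-0.0055,0.0057
P2b.2,grooming total,age,0.0355,0.0023
P2b.2,grooming total,sex,-0.2042,0.1020
P2b.2,grooming total,age:sex,-0.0126,0.0029
P2c.1,proximity,age,0.0007,0.0013
P2c.1,proximity,sex,-0.0922,0.0641
P2c.1,proximity,age:sex,0.0021,0.0017
P2c.1,grooming given,age,0.0346,0.0032
P2c.1,grooming given,sex,-1.1815,0.1887
P2c.1,grooming given,age:sex,0.0060,0.0044
P2c.1,grooming received,age,0.0119,0.0027
P2c.1,grooming received,sex,-0.1137,0.1339
P2c.1,grooming received,age:sex,0.0023,0.0036
P2c.1,grooming total,age,0.0227,0.0022
P2c.1,grooming total,sex,-0.4327,0.1195
P2c.1,grooming total,age:sex,-0.0010,0.0030
P2c.2,proximity,age,-0.0001,0.0026
P2c.2,proximity,sex,-0.0362,0.1412
P2c.2,proximity,age:sex,0.0018,0.0036
P2c.2,grooming given,age,0.0303,0.0051
P2c.2,grooming given,sex,-1.1021,0.3042
P2c.2,grooming given,age:sex,0.0137,0.0073
P2c.2,grooming received,age,0.0261,0.0054
P2c.2,grooming received,sex,-0.0887,0.2828
P2c.2,grooming received,age:sex,0.0067,0.0070
P2c.2,grooming total,age,0.0275,0.0042
P2c.2,grooming total,sex,-0.5450,0.2297
P2c.2,grooming total,age:sex,0.0090,0.0057
P2c.3,proximity,age,0.0010,0.0012
P2c.3,proximity,sex,-0.1528,0.0627
P2c.3,proximity,age:sex,0.0032,0.0016
P2c.3,grooming given,age,0.0364,0.0029
P2c.3,grooming given,sex,-1.5735,0.1916
P2c.3,grooming given,age:sex,0.0078,0.0044
P2c.3,grooming received,age,0.0080,0.0023
P2c.3,grooming received,sex,-1.9513,0.1537
P2c.3,grooming received,age:sex,0.0210,0.0038
P2c.3,grooming total,age,0.0197,0.0020
P2c.3,grooming total,sex,-1.8453,0.1327
P2c.3,grooming total,age:sex,0.0158,0.0032
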