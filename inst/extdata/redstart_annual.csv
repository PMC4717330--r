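year,density_F,density_C,fledge_F,fledge_C
2001,9,19,2.44,3.40
2002,15,25,1.08,2.81
2003,21,23,1.88,1.44
2004,26,17,2.13,2.20
2005,34,23,0.86,1.00
2006,33,8,1.77,0.60
2007,30,17,2.00,0.67
2008,32,15,1.64,1.10
2009,22,17,2.93,1.80
2010,23,19,1.46,2.17
2011,18,22,0.08,1.00
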