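subject,diagnosis,ts_ratio,median_eol
RA014,IS,0.95,0.023
RA017,IS,1.07,0.027
RA021,IS,0.94,0.161
RA022,IS,0.55,0.047
RA024,IS,1.24,0.084
RA027,IS,0.94,0.094
RA103,IS,0.51,0.044
RA105,IS,1.01,0.076
RA113,IS,0.79,0.070
RA114,IS,0.81,0.067
RA003,CP,0.74,0.069
RA016,CP,0.98,0.054
RA019,CP,0.75,0.081
RA026,CP,0.89,0.065
RA030,CP,1.00,0.161
RA041,CP,0.91,0.226
RA042,CP,0.83,0.234
RA100,CP,0.70,0.081
RA104,CP,0.67,0.054
RA111,CP,0.57,0.144
DMD1,DMD,0.37,NA
DMD2,DMD,0.61,NA
DMD3,DMD,0.78,NA
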