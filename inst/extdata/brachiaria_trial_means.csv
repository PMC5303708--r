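genotype,shb_control,shb_waterlogged,height_control,height_waterlogged,ve_waterlogged
BR12/3809,867,482,40.00,30.83,3.2
BR12/1399,1079,458,48.33,39.17,3.3
BR12/3358,526,444,36.67,30.00,3.2
BR12/1280,800,437,43.33,29.17,3.3
BR12/2321,702,426,31.67,25.00,2.8
BR12/4951,1031,416,38.33,35.00,3.2
BR12/3436,724,398,46.67,43.33,3.3
BR12/2756,561,382,40.83,33.33,3.3
BR12/3377,513,350,34.17,35.83,3.3
BR12/4856,526,346,30.35,31.67,2.8
BR12/4047,501,346,43.33,32.50,2.7
BR12/1535,790,316,41.67,35.83,3.3
BR12/0062,717,290,46.67,33.33,2.7
BR12/5082,455,290,36.67,27.50,3.2
BR12/1188,1011,221,42.50,16.67,1.8
BR12/3659,650,220,41.67,25.00,2.0
BR12/2316,384,183,24.25,15.00,1.5
BR12/1176,648,171,30.00,19.17,2.0
BR12/3018,962,125,32.50,18.33,1.8
cv. Cayman,1221,391,63.33,59.17,4.0
cv. Basilisk,774,283,32.50,19.17,2.7
cv. Marandu,586,327,25.00,20.83,3.3
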