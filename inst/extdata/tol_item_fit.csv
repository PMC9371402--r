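item_id,chisq,p_value
Item_1_2,8.4019,0.3952
Item_3_1,14.8232,0.0627
Item_3_2,7.9789,0.4355
Item_3_3,13.322,0.1012
Item_4_1,4.9713,0.7606
Item_4_2,3.9275,0.8636
Item_4_3,7.2758,0.5072
Item_5_1,9.1146,0.3327
Item_5_2,23.0207,0.0033
Item_5_3,29.703,0.0002
Item_6_1,18.1583,0.0201
Item_6_2,17.2215,0.0279
Item_6_3,10.4865,0.2325
Item_7_1,26.7456,0.0008
Item_7_2,19.8636,0.0109
Item_7_3,24.3304,0.002
Item_8_1,16.5941,0.0346
Item_8_2,3.5923,0.8919
Item_8_3,7.1894,0.5163
Item_9_1,9.9894,0.2658
Item_9_2,17.9461,0.0216
Item_9_3,8.5134,0.385
Item_10_1,11.2503,0.1879
Item_10_2,7.5525,0.4784
Item_10_3,9.3497,0.3137
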