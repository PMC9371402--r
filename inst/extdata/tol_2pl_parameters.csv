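item_id,difficulty,difficulty_se,difficulty_z,discrimination,discrimination_se,discrimination_z
Item_1_2,-4.8904,1.9344,-2.5281,0.9907,0.4987,1.9866
Item_3_1,-4.9173,2.006,-2.4513,1.1036,0.6024,1.8318
Item_3_2,-4.3959,1.4469,-3.0382,1.0487,0.4528,2.316
Item_3_3,-2.957,0.8585,-3.4443,0.6356,0.1981,3.2088
Item_4_1,-2.5104,0.5025,-4.9956,1.0311,0.2511,4.1064
Item_4_2,-2.0959,0.3384,-6.1936,1.3667,0.294,4.649
Item_4_3,-2.1625,0.3542,-6.1046,1.3482,0.2946,4.5768
Item_5_1,-1.4868,0.2948,-5.0429,1.0414,0.2134,4.8809
Item_5_2,-1.1268,0.347,-3.2473,0.6743,0.1731,3.8946
Item_5_3,-0.7598,0.2605,-2.9172,0.7722,0.1812,4.2625
Item_6_1,-0.6452,0.1684,-3.8325,1.3412,0.2423,5.5359
Item_6_2,-0.8772,0.1888,-4.6455,1.3214,0.2396,5.5148
Item_6_3,-0.504,0.1139,-4.4251,2.7899,0.491,5.6826
Item_7_1,0.1914,0.2075,0.9228,0.7322,0.1855,3.9468
Item_7_2,-0.7521,0.1988,-3.7842,1.0973,0.2121,5.1743
Item_7_3,-0.1788,0.1442,-1.2404,1.2702,0.237,5.3586
Item_8_1,0.2875,0.126,2.2826,1.4433,0.2802,5.1509
Item_8_2,0.2639,0.0895,2.9476,2.9337,0.5436,5.397
Item_8_3,0.1208,0.0788,1.5325,5.3265,1.434,3.7145
Item_9_1,0.5437,0.1192,4.5604,1.7809,0.3563,4.9981
Item_9_2,0.9257,0.1589,5.824,1.7362,0.3887,4.4662
Item_9_3,0.7767,0.1279,6.0739,1.9745,0.4043,4.8842
Item_10_1,0.7677,0.1262,6.0855,1.9243,0.397,4.8475
Item_10_2,0.6361,0.0872,7.2932,3.4896,0.8635,4.0411
Item_10_3,0.8017,0.12,6.6781,2.1448,0.4535,4.7295
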