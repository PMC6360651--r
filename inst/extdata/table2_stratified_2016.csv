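variable,level,Cm,Cc,Ci,Cfw,TF,TFR
Region,Tigray,0.648,0.639,0.590,0.888,15.3,3.319
Region,Afar,0.752,0.881,0.660,0.946,15.3,6.329
Region,Amhara,0.698,0.578,0.593,0.863,15.3,3.159
Region,Oromia,0.708,0.711,0.612,0.921,15.3,4.341
Region,Somali,0.760,0.984,0.746,0.962,15.3,8.211
Region,Benishangul,0.748,0.714,0.570,0.966,15.3,4.499
Region,SNNPR,0.687,0.598,0.588,0.908,15.3,3.356
Region,Gambela,0.683,0.637,0.629,0.956,15.3,4.003
Region,Harari,0.642,0.718,0.733,0.952,15.3,4.921
Region,Addis Ababa,0.362,0.437,0.862,0.714,15.3,1.490
Region,Dire Dawa,0.533,0.725,0.625,0.909,15.3,3.359
Wealth quintile,Lowest,0.783,0.808,0.588,0.870,15.3,4.952
Wealth quintile,Second,0.760,0.694,0.581,0.914,15.3,4.285
Wealth quintile,Middle,0.713,0.633,0.583,0.899,15.3,3.619
Wealth quintile,Fourth,0.694,0.591,0.664,0.894,15.3,3.725
Wealth quintile,Highest,0.493,0.518,0.803,0.592,15.3,1.857
Education,No education,0.311,0.694,0.580,0.709,15.3,1.358
Education,Primary,0.608,0.590,0.637,0.766,15.3,2.678
Education,Secondary,0.490,0.481,0.803,0.838,15.3,2.427
Education,Higher,0.338,0.488,0.855,0.860,15.3,1.856
Residence,Urban,0.428,0.496,0.826,0.575,15.3,1.543
Residence,Rural,0.640,0.668,0.592,0.659,15.3,2.552
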