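variable,level,Cm,Cc,Ci,Cfw,TF,TFR
Region,Tigray,0.632,0.788,0.533,0.896,15.3,3.639
Region,Afar,0.801,0.902,0.671,0.958,15.3,7.106
Region,Amhara,0.688,0.655,0.542,0.888,15.3,3.318
Region,Oromia,0.680,0.737,0.608,0.903,15.3,4.210
Region,Somali,0.768,0.960,0.749,0.955,15.3,8.069
Region,Benishangul,0.734,0.722,0.645,0.945,15.3,4.942
Region,SNNPR,0.574,0.738,0.581,0.908,15.3,3.419
Region,Gambela,0.613,0.649,0.578,0.938,15.3,3.300
Region,Harari,0.531,0.659,0.743,0.935,15.3,3.719
Region,Addis Ababa,0.316,0.377,0.901,0.750,15.3,1.232
Region,Dire Dawa,0.505,0.682,0.637,0.915,15.3,3.071
Wealth quintile,Lowest,0.756,0.865,0.548,0.869,15.3,4.765
Wealth quintile,Second,0.712,0.777,0.570,0.907,15.3,4.376
Wealth quintile,Middle,0.701,0.755,0.560,0.892,15.3,4.045
Wealth quintile,Fourth,0.682,0.679,0.645,0.881,15.3,4.026
Wealth quintile,Highest,0.512,0.481,0.697,0.628,15.3,1.649
Education,No education,0.746,0.776,0.560,0.676,15.3,3.353
Education,Primary,0.564,0.638,0.656,0.811,15.3,2.929
Education,Secondary,0.371,0.428,0.897,0.838,15.3,1.826
Education,Higher,0.409,0.351,0,0.838,15.3,0.00
Residence,Urban,0.352,0.470,0.687,0.617,15.3,1.073
Residence,Rural,0.665,0.810,0.570,0.652,15.3,3.063
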