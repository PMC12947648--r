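"age_start","condition","incidence","prevalence","incidence_se","prevalence_se"
40,"cvd",0.0032056236235902,0.0134236243511917,0.00032056236235902,0.00134236243511917
45,"cvd",0.0042203018325368,0.0189424706256807,0.00042203018325368,0.00189424706256807
50,"cvd",0.00555615681973474,0.0266689426286498,0.000555615681973474,0.00266689426286498
55,"cvd",0.00731485088755571,0.0374267464127686,0.000731485088755571,0.00374267464127686
60,"cvd",0.00963022557554974,0.0522909327832977,0.000963022557554974,0.00522909327832977
65,"cvd",0.0126784873761059,0.0726131621340072,0.00126784873761059,0.00726131621340072
70,"cvd",0.0166916175415654,0.1,0.00166916175415654,0.01
75,"cvd",0.0219750265066293,0.136199092862667,0.00219750265066293,0.0136199092862667
80,"cvd",0.0289307964770065,0.182839833157374,0.00289307964770065,0.0182839833157374
85,"cvd",0.0380882810103312,0.240996390398939,0.00380882810103312,0.0240996390398939
90,"cvd",0.050144390303079,0.310619521504333,0.0050144390303079,0.0310619521504333
95,"cvd",0.066016628006538,0.390020849925291,0.0066016628006538,0.0390020849925291
100,"cvd",0.0869129158219321,0.475712983977227,0.00869129158219321,0.0475712983977227
40,"cancer",0.00339595525644939,0.00775574599784986,0.000339595525644939,0.000775574599784986
45,"cancer",0.00425283191082274,0.0109702720857056,0.000425283191082274,0.00109702720857056
50,"cancer",0.00532591801006897,0.0154963161338753,0.000532591801006897,0.00154963161338753
55,"cancer",0.00666976810858474,0.021848435537712,0.000666976810858474,0.0021848435537712
60,"cancer",0.00835270211411272,0.0307231060122696,0.000835270211411272,0.00307231060122696
65,"cancer",0.0104602785990872,0.0430439691891632,0.00104602785990872,0.00430439691891632
70,"cancer",0.0130996445073325,0.06,0.00130996445073325,0.006
75,"cancer",0.0164049823905704,0.0830556960979665,0.00164049823905704,0.00830556960979665
80,"cancer",0.0205443321064389,0.113897338341204,0.00205443321064389,0.0113897338341204
85,"cancer",0.0257281337858833,0.154264850736841,0.00257281337858833,0.0154264850736841
90,"cancer",0.032219926385285,0.205619480255185,0.0032219926385285,0.0205619480255185
95,"cancer",0.040349745726322,0.268639667610277,0.0040349745726322,0.0268639667610277
100,"cancer",0.0505309031656387,0.342643641490954,0.00505309031656387,0.0342643641490954
40,"t2d",0.00219524654437611,0.00640380218474733,0.000219524654437611,0.000640380218474733
45,"t2d",0.00248754022586008,0.00906310588426461,0.000248754022586008,0.000906310588426461
50,"t2d",0.00281875235887485,0.0128124969002886,0.000281875235887485,0.00128124969002886
55,"t2d",0.00319406487503751,0.0180846963772392,0.000319406487503751,0.00180846963772392
60,"t2d",0.00361934967214384,0.0254703731988822,0.000361934967214384,0.00254703731988822
65,"t2d",0.00410126048209772,0.0357624584824764,0.000410126048209772,0.00357624584824764
70,"t2d",0.00464733697091313,0.05,0.000464733697091313,0.005
75,"t2d",0.00526612269947049,0.0694971768527708,0.000526612269947049,0.00694971768527708
80,"t2d",0.00596729879056508,0.0958302277324592,0.000596729879056508,0.00958302277324592
85,"t2d",0.00676183539351637,0.130739167837737,0.000676183539351637,0.0130739167837737
90,"t2d",0.00766216331605558,0.175890904120389,0.000766216331605559,0.0175890904120389
95,"t2d",0.00868236850873377,0.232465968099887,0.000868236850873377,0.0232465968099887
100,"t2d",0.0098384124446278,0.300600708117849,0.00098384124446278,0.0300600708117849
40,"copd",0.000602388423824404,0.00377302259943517,6.02388423824404e-05,0.000377302259943517
45,"copd",0.000773482046909002,0.0053457215362424,7.73482046909002e-05,0.00053457215362424
50,"copd",0.000993170607582819,0.00756898377901786,9.93170607582819e-05,0.000756898377901786
55,"copd",0.00127525630324355,0.0107069377550499,0.000127525630324355,0.00107069377550499
60,"copd",0.00163746150615596,0.0151259986136506,0.000163746150615596,0.00151259986136506
65,"copd",0.00210254219275205,0.0213296093217926,0.000210254219275205,0.00213296093217926
70,"copd",0.00269971761515201,0.03,0.000269971761515201,0.003
75,"copd",0.00346650603573479,0.0420434550287984,0.000346650603573479,0.00420434550287984
80,"copd",0.00445108185698494,0.0586295065927331,0.000445108185698494,0.00586295065927331
85,"copd",0.00571530223612633,0.0812040686730423,0.000571530223612633,0.00812040686730423
90,"copd",0.00733859333523849,0.111441698773411,0.000733859333523849,0.0111441698773411
95,"copd",0.00942294036518148,0.15108728061806,0.000942294036518148,0.015108728061806
100,"copd",0.0120992949288259,0.201636298178402,0.00120992949288259,0.0201636298178402
40,"dementia",4.28167617338316e-05,0.0012354055041162,4.28167617338316e-06,0.00012354055041162
45,"dementia",7.42122814904729e-05,0.00175221670549244,7.42122814904729e-06,0.000175221670549244
50,"dementia",0.000128628660856187,0.00248468936452502,1.28628660856187e-05,0.000248468936452502
55,"dementia",0.000222946014613227,0.00352227446779941,2.22946014613227e-05,0.000352227446779941
60,"dementia",0.000386421852649885,0.00499097835644503,3.86421852649885e-05,0.000499097835644503
65,"dementia",0.000669766842275323,0.00706775281303326,6.69766842275323e-05,0.000706775281303327
70,"dementia",0.00116087540064122,0.01,0.000116087540064122,0.001
75,"dementia",0.00201209079152941,0.0141314551432831,0.000201209079152941,0.00141314551432831
80,"dementia",0.00348746243664155,0.0199354311021607,0.000348746243664155,0.00199354311021607
85,"dementia",0.00604465479300815,0.0280553408280627,0.000604465479300815,0.00280553408280627
90,"dementia",0.010476916161948,0.0393497850486859,0.0010476916161948,0.00393497850486859
95,"dementia",0.01815914655564,0.0549341272746179,0.00181591465556401,0.00549341272746179
100,"dementia",0.0314743955694594,0.0762010055900112,0.00314743955694594,0.00762010055900112
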