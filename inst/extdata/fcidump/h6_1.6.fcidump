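 &FCI NORB=6,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 3.2838717738465234e-01   1   1   1   1
 1.1991344629720886e-01   2   1   2   1
 2.5847019566631491e-01   2   2   1   1
 3.0272268906394872e-01   2   2   2   2
 6.6861139445025239e-02   3   1   1   1
-4.3685352809858434e-02   3   1   2   2
 1.0760198867263100e-01   3   1   3   1
-9.5766323350864074e-02   3   2   2   1
 1.1632087103655253e-01   3   2   3   2
 2.8742750639481085e-01   3   3   1   1
 2.6345861071830784e-01   3   3   2   2
 2.6015199342446362e-02   3   3   3   1
 2.9077388236105561e-01   3   3   3   3
 4.3407720011971684e-02   4   1   2   1
 1.8598443110838879e-02   4   1   3   2
 8.7522908799896174e-02   4   1   4   1
 5.9904478295931984e-02   4   2   1   1
-8.5180435997706381e-06   4   2   2   2
 5.3251781093985956e-02   4   2   3   1
 8.7203386194928954e-05   4   2   3   3
 8.2660901664993541e-02   4   2   4   2
 6.7552354025510478e-02   4   3   2   1
-6.1328768554392621e-02   4   3   3   2
 1.4756958494041588e-02   4   3   4   1
 1.0330499889668596e-01   4   3   4   3
 2.9018548262125832e-01   4   4   1   1
 2.6508458204360108e-01   4   4   2   2
 2.6599838282634673e-02   4   4   3   1
 2.9033603639368960e-01   4   4   3   3
 2.7464302226905693e-03   4   4   4   2
 2.9704651199698245e-01   4   4   4   4
-8.7974650337763211e-03   5   1   1   1
-3.1673430727815644e-02   5   1   2   2
 2.7104239719953741e-02   5   1   3   1
 1.8583099078924151e-02   5   1   3   3
-4.0238846518397479e-02   5   1   4   2
 1.7043051776321570e-02   5   1   4   4
 5.8198648616020407e-02   5   1   5   1
-3.3579510513534930e-02   5   2   2   1
-6.0009131060077573e-03   5   2   3   2
-5.6786721108406914e-02   5   2   4   1
 5.1860681788652635e-02   5   2   4   3
 1.0342343646034104e-01   5   2   5   2
 6.1858253175883213e-02   5   3   1   1
 1.7113165971853965e-03   5   3   2   2
 5.3990666215742798e-02   5   3   3   1
 3.9475018386878466e-03   5   3   3   3
 8.1987129142499893e-02   5   3   4   2
 1.9050446689788281e-03   5   3   4   4
-3.9415953905006372e-02   5   3   5   1
 8.4919654473845807e-02   5   3   5   3
-9.7041463101591091e-02   5   4   2   1
 1.1598140028736148e-01   5   4   3   2
 1.7077100089718120e-02   5   4   4   1
-6.3328358624719444e-02   5   4   4   3
-6.9852130985395720e-03   5   4   5   2
 1.2077563385100343e-01   5   4   5   4
 2.6571650921259021e-01   5   5   1   1
 3.0932414885694520e-01   5   5   2   2
-4.2802843676860942e-02   5   5   3   1
 2.7147573668162872e-01   5   5   3   3
-1.3858379472051537e-04   5   5   4   2
 2.7487792673554690e-01   5   5   4   4
-3.1664623111409669e-02   5   5   5   1
 1.3273398397533019e-03   5   5   5   3
 3.2255057091951217e-01   5   5   5   5
-6.7618249061566983e-04   6   1   2   1
-2.2696247136987688e-02   6   1   3   2
-3.1761880511019421e-02   6   1   4   1
-6.1655038459347562e-02   6   1   4   3
-4.6739525873837375e-02   6   1   5   2
-2.1904123812502355e-02   6   1   5   4
 8.1375813946382422e-02   6   1   6   1
 9.8847964954921451e-03   6   2   1   1
 3.2804592609074888e-02   6   2   2   2
-2.6798449523967954e-02   6   2   3   1
-1.5993621141666425e-02   6   2   3   3
 3.9535611666516944e-02   6   2   4   2
-1.8033163573709435e-02   6   2   4   4
-5.7703332233327631e-02   6   2   5   1
 4.1384466793425508e-02   6   2   5   3
 3.3055917101536401e-02   6   2   5   5
 5.9273093884460573e-02   6   2   6   2
-4.4638911410160818e-02   6   3   2   1
-1.6075106362817431e-02   6   3   3   2
-8.7194800342056608e-02   6   3   4   1
-1.4801098448670932e-02   6   3   4   3
 5.8698433185928774e-02   6   3   5   2
-1.8010512136614084e-02   6   3   5   4
 3.1036184122179171e-02   6   3   6   1
 9.0499541034944508e-02   6   3   6   3
-6.9540452961902671e-02   6   4   1   1
 4.2458216086826657e-02   6   4   2   2
-1.0908107927454887e-01   6   4   3   1
-2.7026979516392408e-02   6   4   3   3
-5.6124024531053911e-02   6   4   4   2
-2.8216132601994608e-02   6   4   4   4
-2.6436548833097314e-02   6   4   5   1
-5.6871329689969427e-02   6   4   5   3
 4.5212800282189172e-02   6   4   5   5
 2.6764904110921525e-02   6   4   6   2
 1.1540597812127137e-01   6   4   6   4
-1.2476616890911843e-01   6   5   2   1
 1.0111138769165759e-01   6   5   3   2
-4.4519417396148821e-02   6   5   4   1
-7.1768935413636437e-02   6   5   4   3
 3.4758119196894331e-02   6   5   5   2
 1.0371063636262551e-01   6   5   5   4
 7.9999124972731240e-04   6   5   6   1
 4.7421784257012031e-02   6   5   6   3
 1.3500895824182604e-01   6   5   6   5
 3.4264924851401007e-01   6   6   1   1
 2.7092026999053115e-01   6   6   2   2
 6.9322146337913629e-02   6   6   3   1
 3.0171549823847887e-01   6   6   3   3
 6.2928055054622553e-02   6   6   4   2
 3.0597066474969647e-01   6   6   4   4
-9.6065997164031282e-03   6   6   5   1
 6.6027052569062217e-02   6   6   5   3
 2.8202989568795783e-01   6   6   5   5
 1.1214411281528256e-02   6   6   6   2
-7.4133680150212794e-02   6   6   6   4
 3.6614898943800772e-01   6   6   6   6
-1.6143199691270851e+00   1   1   0   0
-1.4673731036536883e+00   2   2   0   0
-1.0127195651926217e-01   3   1   0   0
-1.4253172022702822e+00   3   3   0   0
-1.3789589386065490e-01   4   2   0   0
-1.3419986171206770e+00   4   4   0   0
 5.5389284034004387e-02   5   1   0   0
-1.0998331477100375e-01   5   3   0   0
-1.2239167415392280e+00   5   5   0   0
-3.7338232170456093e-02   6   2   0   0
 1.0119106548763003e-01   6   4   0   0
-1.2533568012934624e+00   6   6   0   0
 2.8774010842850628e+00   0   0   0   0
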