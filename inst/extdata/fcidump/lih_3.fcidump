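 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6599422897669156e+00   1   1   1   1
 1.0296390411328910e-01   2   1   1   1
 1.0497569120561896e-02   2   1   2   1
 2.7032272246398725e-01   2   2   1   1
-1.1987387661189102e-04   2   2   2   1
 4.0097954540532460e-01   2   2   2   2
-1.4286471907564399e-01   3   1   1   1
-1.2152134168982587e-02   3   1   2   1
-7.3829360886871424e-03   3   1   2   2
 2.1292529362233227e-02   3   1   3   1
-6.5681321867843562e-02   3   2   1   1
-2.7220162613377902e-03   3   2   2   1
 8.9533342530470086e-02   3   2   2   2
 1.1669425603709185e-03   3   2   3   1
 6.1030261872110379e-02   3   2   3   2
 3.6719514170745032e-01   3   3   1   1
 6.9978874788181010e-03   3   3   2   1
 2.2737001579961941e-01   3   3   2   2
-9.4976490765212595e-04   3   3   3   1
-1.4653729047727129e-02   3   3   3   2
 2.9601123422763131e-01   3   3   3   3
 9.7815076414692823e-03   4   1   4   1
-7.7590055201894282e-03   4   2   4   1
 2.1834584804896091e-02   4   2   4   2
 1.0505566912903812e-02   4   3   4   1
-2.4242215601779377e-02   4   3   4   2
 4.0502885995930188e-02   4   3   4   3
 3.9635243395982528e-01   4   4   1   1
 3.5771471895867722e-03   4   4   2   1
 2.1559423107467196e-01   4   4   2   2
-5.0305342177976295e-03   4   4   3   1
-3.6159738137530498e-02   4   4   3   2
 2.6639743894991830e-01   4   4   3   3
 3.1294546903540305e-01   4   4   4   4
 9.7815076414692875e-03   5   1   5   1
-7.7590055201894317e-03   5   2   5   1
 2.1834584804896102e-02   5   2   5   2
 1.0505566912903816e-02   5   3   5   1
-2.4242215601779388e-02   5   3   5   2
 4.0502885995930202e-02   5   3   5   3
 1.6869136896862875e-02   5   4   5   4
 3.9635243395982545e-01   5   5   1   1
 3.5771471895867605e-03   5   5   2   1
 2.1559423107467204e-01   5   5   2   2
-5.0305342177976355e-03   5   5   3   1
-3.6159738137530512e-02   5   5   3   2
 2.6639743894991841e-01   5   5   3   3
 2.7920719524167742e-01   5   5   4   4
 3.1294546903540338e-01   5   5   5   5
 5.0215374173086413e-02   6   1   1   1
 7.1075416592366082e-03   6   1   2   1
-5.9020856846184432e-03   6   1   2   2
-2.5627376566619842e-03   6   1   3   1
-3.2499902682495184e-03   6   1   3   2
 9.9551585921708284e-03   6   1   3   3
 1.3278533756444365e-03   6   1   4   4
 1.3278533756444374e-03   6   1   5   5
 9.2603998945485298e-03   6   1   6   1
 9.1285413255807718e-02   6   2   1   1
 2.5352249458670552e-04   6   2   2   1
-9.1113941752594255e-02   6   2   2   2
-5.1777921680245175e-03   6   2   3   1
-7.3399503799890492e-02   6   2   3   2
-3.3996408305518714e-03   6   2   3   3
 4.9405839576675395e-02   6   2   4   4
 4.9405839576675416e-02   6   2   5   5
-3.6187490876255011e-03   6   2   6   1
 1.2159369183100611e-01   6   2   6   2
 4.3310620952341776e-02   6   3   1   1
 2.2781543571919402e-03   6   3   2   1
-8.1452931052840419e-02   6   3   2   2
 3.6686326667427147e-03   6   3   3   1
-4.9984925966027917e-02   6   3   3   2
 3.1224857043827839e-02   6   3   3   3
 2.1882971743330665e-02   6   3   4   4
 2.1882971743330679e-02   6   3   5   5
 6.3705091646744944e-03   6   3   6   1
 5.1853668391846873e-02   6   3   6   2
 5.8249338105986412e-02   6   3   6   3
-4.0950312024210121e-03   6   4   4   1
 1.4555287667421556e-02   6   4   4   2
-6.8408549386967474e-03   6   4   4   3
 1.6585285846832058e-02   6   4   6   4
-4.0950312024210138e-03   6   5   5   1
 1.4555287667421563e-02   6   5   5   2
-6.8408549386967492e-03   6   5   5   3
 1.6585285846832064e-02   6   5   6   5
 3.4233435062139395e-01   6   6   1   1
 9.2099169886763956e-04   6   6   2   1
 3.4816925742905502e-01   6   6   2   2
-8.1617173029161529e-03   6   6   3   1
 4.6994184114541905e-02   6   6   3   2
 2.5210569857762455e-01   6   6   3   3
 2.4963146782547482e-01   6   6   4   4
 2.4963146782547493e-01   6   6   5   5
-5.0490135830907534e-03   6   6   6   1
-3.5558561445124440e-02   6   6   6   2
-4.1495059788282385e-02   6   6   6   3
 3.3772526941168612e-01   6   6   6   6
-4.5739980422814686e+00   1   1   0   0
-1.0284403023559696e-01   2   1   0   0
-1.1066143065373806e+00   2   2   0   0
 1.5490857499173435e-01   3   1   0   0
 2.9677167026086713e-02   3   2   0   0
-1.0495781581640036e+00   3   3   0   0
-1.0411792934886026e+00   4   4   0   0
-1.0411792934886031e+00   5   5   0   0
-3.8157680307806863e-02   6   1   0   0
-8.4349343094325693e-02   6   2   0   0
 3.2237874684776019e-04   6   3   0   0
-1.0158151319270934e+00   6   6   0   0
 5.2917721090300007e-01   0   0   0   0
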