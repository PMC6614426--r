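 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6602306073692930e+00   1   1   1   1
 1.1131089818192032e-01   2   1   1   1
 1.1838736744691514e-02   2   1   2   1
 2.5594555487926840e-01   2   2   1   1
 1.2581208971809762e-03   2   2   2   1
 3.7431031120562164e-01   2   2   2   2
-1.4139214551041709e-01   3   1   1   1
-1.3746319945737818e-02   3   1   2   1
-5.4680086926997785e-03   3   1   2   2
 1.9736922389450219e-02   3   1   3   1
-9.9940660465335993e-02   3   2   1   1
-3.0509862378254719e-03   3   2   2   1
 1.1575333620710981e-01   3   2   2   2
 2.2747525637707021e-03   3   2   3   1
 1.1795042259835892e-01   3   2   3   2
 3.3100587891468375e-01   3   3   1   1
 5.5131488847982380e-03   3   3   2   1
 2.6573082748639676e-01   3   3   2   2
-2.7907717104026855e-03   3   3   3   1
 1.9128736840781882e-02   3   3   3   2
 2.7623208032566937e-01   3   3   3   3
 9.7708775428954758e-03   4   1   4   1
-8.3546920163059986e-03   4   2   4   1
 2.4070759425549895e-02   4   2   4   2
 1.0475401451347888e-02   4   3   4   1
-2.7520108185472063e-02   4   3   4   2
 3.8346758971001683e-02   4   3   4   3
 3.9635709070829855e-01   4   4   1   1
 3.8410710106978343e-03   4   4   2   1
 2.0301872810486390e-01   4   4   2   2
-4.9171556694346565e-03   4   4   3   1
-5.7917065652466154e-02   4   4   3   2
 2.4504166160937219e-01   4   4   3   3
 3.1294546903540327e-01   4   4   4   4
 9.7708775428954706e-03   5   1   5   1
-8.3546920163059951e-03   5   2   5   1
 2.4070759425549881e-02   5   2   5   2
 1.0475401451347883e-02   5   3   5   1
-2.7520108185472049e-02   5   3   5   2
 3.8346758971001663e-02   5   3   5   3
 1.6869136896862879e-02   5   4   5   4
 3.9635709070829833e-01   5   5   1   1
 3.8410710106978304e-03   5   5   2   1
 2.0301872810486382e-01   5   5   2   2
-4.9171556694346487e-03   5   5   3   1
-5.7917065652466140e-02   5   5   3   2
 2.4504166160937210e-01   5   5   3   3
 2.7920719524167736e-01   5   5   4   4
 3.1294546903540299e-01   5   5   5   5
 2.8073716777845863e-02   6   1   1   1
 4.7980189687178198e-03   6   1   2   1
-5.0706181255419673e-03   6   1   2   2
-4.5171563177110282e-04   6   1   3   1
-2.9621114985866484e-03   6   1   3   2
 6.8624433552216804e-03   6   1   3   3
 6.9532004218276176e-04   6   1   4   4
 6.9532004218276144e-04   6   1   5   5
 8.8886807382385410e-03   6   1   6   1
 7.6182956398429980e-02   6   2   1   1
-9.8420820482830572e-05   6   2   2   1
-6.7122091653297106e-02   6   2   2   2
-4.3545570596881132e-03   6   2   3   1
-8.2010048628237867e-02   6   2   3   2
-3.1695293885733077e-02   6   2   3   3
 4.3718032830680660e-02   6   2   4   4
 4.3718032830680639e-02   6   2   5   5
-5.9808775336452260e-03   6   2   6   1
 8.5458654550271906e-02   6   2   6   2
 5.1459216958560643e-02   6   3   1   1
 2.3817372370984078e-03   6   3   2   1
-8.6743839034573278e-02   6   3   2   2
 2.9089854954952830e-03   6   3   3   1
-7.6873314535003665e-02   6   3   3   2
 4.0155519852298855e-03   6   3   3   3
 2.8438427302525684e-02   6   3   4   4
 2.8438427302525670e-02   6   3   5   5
 8.6359808165435304e-03   6   3   6   1
 3.4249258886522888e-02   6   3   6   2
 7.3410949655726185e-02   6   3   6   3
-2.3670601617070551e-03   6   4   4   1
 9.9144346421415844e-03   6   4   4   2
-2.4736522803710487e-03   6   4   4   3
 1.5711556867450117e-02   6   4   6   4
-2.3670601617070538e-03   6   5   5   1
 9.9144346421415810e-03   6   5   5   2
-2.4736522803710461e-03   6   5   5   3
 1.5711556867450110e-02   6   5   6   5
 3.5900480124218653e-01   6   6   1   1
 2.4133946098677419e-03   6   6   2   1
 2.8079221802406229e-01   6   6   2   2
-6.1027150043308437e-03   6   6   3   1
 1.1057307253308977e-02   6   6   3   2
 2.5953282866874916e-01   6   6   3   3
 2.5773689309226328e-01   6   6   4   4
 2.5773689309226316e-01   6   6   5   5
-3.6664387987904814e-03   6   6   6   1
 1.1309036600835414e-02   6   6   6   2
-1.2647725340575665e-02   6   6   6   3
 2.9678966670322432e-01   6   6   6   6
-4.5447758059932486e+00   1   1   0   0
-1.1256901904232464e-01   2   1   0   0
-1.0194848463038124e+00   2   2   0   0
 1.4927717665535351e-01   3   1   0   0
 7.0381664250662709e-02   3   2   0   0
-1.0109016197713663e+00   3   3   0   0
-1.0171222372696536e+00   4   4   0   0
-1.0171222372696531e+00   5   5   0   0
-1.8030901322943195e-02   6   1   0   0
-8.0445802254886789e-02   6   2   0   0
-1.1892520525248966e-02   6   3   0   0
-1.0055506995353269e+00   6   6   0   0
 4.4098100908583332e-01   0   0   0   0
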