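 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6602930324652674e+00   1   1   1   1
 1.1363216440519776e-01   2   1   1   1
 1.2235680841152919e-02   2   1   2   1
 2.5261838238646100e-01   2   2   1   1
 1.6143701989715987e-03   2   2   2   1
 3.6747310073286571e-01   2   2   2   2
-1.4049741799108376e-01   3   1   1   1
-1.4138588664484076e-02   3   1   2   1
-4.9594263419770121e-03   3   1   2   2
 1.9153790800874475e-02   3   1   3   1
-1.0996502374881890e-01   3   2   1   1
-3.1244033275964764e-03   3   2   2   1
 1.2257456172297984e-01   3   2   2   2
 2.6239025479144603e-03   3   2   3   1
 1.3731697708310761e-01   3   2   3   2
 3.1813603353817299e-01   3   3   1   1
 5.0561781099946971e-03   3   3   2   1
 2.7852090337580515e-01   3   3   2   2
-3.2673983248118826e-03   3   3   3   1
 3.5406078147569423e-02   3   3   3   2
 2.7612163313314153e-01   3   3   3   3
 9.7686322917568541e-03   4   1   4   1
-8.5182251920065608e-03   4   2   4   1
 2.4762522156834759e-02   4   2   4   2
 1.0432766184185730e-02   4   3   4   1
-2.8319076018056527e-02   4   3   4   2
 3.7478833265187604e-02   4   3   4   3
 3.9635815812794395e-01   4   4   1   1
 3.9194979907671351e-03   4   4   2   1
 1.9979287105055790e-01   4   4   2   2
-4.8690380484192044e-03   4   4   3   1
-6.4595069686014334e-02   4   4   3   2
 2.3711953853195572e-01   4   4   3   3
 3.1294546903540282e-01   4   4   4   4
 9.7686322917568593e-03   5   1   5   1
-8.5182251920065660e-03   5   2   5   1
 2.4762522156834776e-02   5   2   5   2
 1.0432766184185739e-02   5   3   5   1
-2.8319076018056544e-02   5   3   5   2
 3.7478833265187632e-02   5   3   5   3
 1.6869136896862858e-02   5   4   5   4
 3.9635815812794423e-01   5   5   1   1
 3.9194979907671420e-03   5   5   2   1
 1.9979287105055801e-01   5   5   2   2
-4.8690380484192010e-03   5   5   3   1
-6.4595069686014375e-02   5   5   3   2
 2.3711953853195594e-01   5   5   3   3
 2.7920719524167736e-01   5   5   4   4
 3.1294546903540327e-01   5   5   5   5
-2.1229529188326778e-02   6   1   1   1
-3.9756492501392474e-03   6   1   2   1
 4.7614614087304738e-03   6   1   2   2
-5.6676204752204819e-05   6   1   3   1
 2.6781525607283627e-03   6   1   3   2
-5.6390911733408371e-03   6   1   3   3
-4.9269016583618403e-04   6   1   4   4
-4.9269016583618436e-04   6   1   5   5
 8.9736571335496309e-03   6   1   6   1
-6.8202527644662600e-02   6   2   1   1
 1.8822068155486665e-04   6   2   2   1
 5.7546450049951604e-02   6   2   2   2
 3.8597088079497808e-03   6   2   3   1
 7.8231490604191559e-02   6   2   3   2
 3.6094038341180787e-02   6   2   3   3
-3.9703246599614522e-02   6   2   4   4
-3.9703246599614550e-02   6   2   5   5
-6.6808756654229105e-03   6   2   6   1
 7.2111120956876093e-02   6   2   6   2
-4.9996965589190916e-02   6   3   1   1
-2.2837519252933264e-03   6   3   2   1
 8.2396305560419048e-02   6   3   2   2
-2.4952436184965177e-03   6   3   3   1
 7.8958026985842922e-02   6   3   3   2
 5.6962836978775890e-03   6   3   3   3
-2.8163907372893662e-02   6   3   4   4
-2.8163907372893683e-02   6   3   5   5
 9.2074590830219828e-03   6   3   6   1
 2.2828515750326635e-02   6   3   6   2
 7.1368867461132940e-02   6   3   6   3
 1.8315638814140440e-03   6   4   4   1
-8.2434010388021204e-03   6   4   4   2
 1.3429822710889360e-03   6   4   4   3
 1.5754647189809685e-02   6   4   6   4
 1.8315638814140453e-03   6   5   5   1
-8.2434010388021256e-03   6   5   5   2
 1.3429822710889368e-03   6   5   5   3
 1.5754647189809699e-02   6   5   6   5
 3.6657545167251004e-01   6   6   1   1
 2.8586102673372974e-03   6   6   2   1
 2.6030882943937567e-01   6   6   2   2
-5.5922819241321624e-03   6   6   3   1
-6.6505384404268184e-03   6   6   3   2
 2.5512460737005521e-01   6   6   3   3
 2.6186466430718702e-01   6   6   4   4
 2.6186466430718719e-01   6   6   5   5
 3.0180249463803059e-03   6   6   6   1
-2.0539239749745020e-02   6   6   6   2
 1.9111149675543587e-03   6   6   6   3
 2.9295711226978821e-01   6   6   6   6
-4.5370790883212786e+00   1   1   0   0
-1.1524653463453567e-01   2   1   0   0
-9.9764359814128201e-01   2   2   0   0
 1.4729186735629718e-01   3   1   0   0
 8.3216897254785177e-02   3   2   0   0
-9.9706316288624885e-01   3   3   0   0
-1.0104964447417104e+00   4   4   0   0
-1.0104964447417111e+00   5   5   0   0
 1.1894827095863637e-02   6   1   0   0
 7.4882955888359956e-02   6   2   0   0
 1.3376134193410981e-02   6   3   0   0
-1.0030470844733419e+00   6   6   0   0
 4.1777148229184213e-01   0   0   0   0
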