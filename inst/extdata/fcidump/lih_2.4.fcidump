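 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6594953689438192e+00   1   1   1   1
 9.7652866340045608e-02   2   1   1   1
 9.8335484486340007e-03   2   1   2   1
 2.9720719794493450e-01   2   2   1   1
-1.8306260242809361e-03   2   2   2   1
 4.3490551466214172e-01   2   2   2   2
-1.4256132999545368e-01   3   1   1   1
-1.0836373029360972e-02   3   1   2   1
-9.8161986733232166e-03   3   1   2   2
 2.2003235675455098e-02   3   1   3   1
-3.7136219468108758e-02   3   2   1   1
-2.4992454978009226e-03   3   2   2   1
 6.6611794444534259e-02   3   2   2   2
 4.4888749998137751e-04   3   2   3   1
 2.8694858338744206e-02   3   2   3   2
 3.8683688373815273e-01   3   3   1   1
 8.2432260630491729e-03   3   3   2   1
 2.1232508301561767e-01   3   3   2   2
 4.4638600307082187e-04   3   3   3   1
-1.7296332846838333e-02   3   3   3   2
 3.2117147207692665e-01   3   3   3   3
 9.7985262336615538e-03   4   1   4   1
-7.3116827551803071e-03   4   2   4   1
 2.0852893146107176e-02   4   2   4   2
 1.0439297955774980e-02   4   3   4   1
-2.1222647995658993e-02   4   3   4   2
 4.1368192869066067e-02   4   3   4   3
 3.9634531301158188e-01   4   4   1   1
 3.4885775267395939e-03   4   4   2   1
 2.3463503828550689e-01   4   4   2   2
-5.0750978177188360e-03   4   4   3   1
-1.8975577478883045e-02   4   4   3   2
 2.7735097675642978e-01   4   4   3   3
 3.1294546903540282e-01   4   4   4   4
 9.7985262336615538e-03   5   1   5   1
-7.3116827551803071e-03   5   2   5   1
 2.0852893146107179e-02   5   2   5   2
 1.0439297955774982e-02   5   3   5   1
-2.1222647995658997e-02   5   3   5   2
 4.1368192869066067e-02   5   3   5   3
 1.6869136896862865e-02   5   4   5   4
 3.9634531301158193e-01   5   5   1   1
 3.4885775267396008e-03   5   5   2   1
 2.3463503828550694e-01   5   5   2   2
-5.0750978177188360e-03   5   5   3   1
-1.8975577478883014e-02   5   5   3   2
 2.7735097675642983e-01   5   5   3   3
 2.7920719524167725e-01   5   5   4   4
 3.1294546903540299e-01   5   5   5   5
-6.5835716144998530e-02   6   1   1   1
-8.6585422484492004e-03   6   1   2   1
 6.9374577877649307e-03   6   1   2   2
 4.2460936935040288e-03   6   1   3   1
 2.9324432230428770e-03   6   1   3   2
-1.1497244522337394e-02   6   1   3   3
-1.6354819660929511e-03   6   1   4   4
-1.6354819660929513e-03   6   1   5   5
 1.0438544582425824e-02   6   1   6   1
-8.7335685326860771e-02   6   2   1   1
-9.1692683294690891e-04   6   2   2   1
 1.0332335372601421e-01   6   2   2   2
 4.7576248808898691e-03   6   2   3   1
 5.1928977754728274e-02   6   2   3   2
-1.6336785930810522e-02   6   2   3   3
-4.2982230746257136e-02   6   2   4   4
-4.2982230746257143e-02   6   2   5   5
-1.6608221999680328e-03   6   2   6   1
 1.3223124282372595e-01   6   2   6   2
-2.8335335128720131e-02   6   3   1   1
-2.1194032473799995e-03   6   3   2   1
 6.3892851967470576e-02   6   3   2   2
-3.8812388186711903e-03   6   3   3   1
 2.4116730672312653e-02   6   3   3   2
-3.7211060801311729e-02   6   3   3   3
-1.1672616852890449e-02   6   3   4   4
-1.1672616852890449e-02   6   3   5   5
 4.7820856796893024e-03   6   3   6   1
 4.4189431529761972e-02   6   3   6   2
 3.6747395820341124e-02   6   3   6   3
 5.4331195320991973e-03   6   4   4   1
-1.7503945135299660e-02   6   4   4   2
 1.0694412371957163e-02   6   4   4   3
 1.8459544896377564e-02   6   4   6   4
 5.4331195320991973e-03   6   5   5   1
-1.7503945135299660e-02   6   5   5   2
 1.0694412371957163e-02   6   5   5   3
 1.8459544896377567e-02   6   5   6   5
 3.4623250499760833e-01   6   6   1   1
-2.8641457121025653e-04   6   6   2   1
 4.0347124271119844e-01   6   6   2   2
-1.0069107706430170e-02   6   6   3   1
 5.1197108042836087e-02   6   6   3   2
 2.3983285900990092e-01   6   6   3   3
 2.5389904134650265e-01   6   6   4   4
 2.5389904134650265e-01   6   6   5   5
 5.3200168759365554e-03   6   6   6   1
 8.1181882217737256e-02   6   6   6   2
 4.7389151760386231e-02   6   6   6   3
 3.9562596578237424e-01   6   6   6   6
-4.6178201794734433e+00   1   1   0   0
-9.5822240319812596e-02   2   1   0   0
-1.2363876831347318e+00   2   2   0   0
 1.5969448184240798e-01   3   1   0   0
-3.1757285117447326e-03   3   2   0   0
-1.0806743889388961e+00   3   3   0   0
-1.0736566457306913e+00   4   4   0   0
-1.0736566457306913e+00   5   5   0   0
 5.1043873742312722e-02   6   1   0   0
 6.2689474702409875e-02   6   2   0   0
-1.4939962218947209e-02   6   3   0   0
-1.0215164909298908e+00   6   6   0   0
 6.6147151362875001e-01   0   0   0   0
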