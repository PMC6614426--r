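 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6264810811258272e+00   1   1   1   1
-1.8643193358307503e-01   2   1   1   1
 4.5817561352645621e-02   2   1   2   1
 5.1293267932855513e-01   2   2   1   1
 1.5934810012018158e-02   2   2   2   1
 5.1657763622314368e-01   2   2   2   2
-1.1052865659194078e-01   3   1   1   1
 1.2509657663418751e-02   3   1   2   1
-2.8723357052150789e-02   3   1   2   2
 1.6923445326886246e-02   3   1   3   1
-5.3118785380819253e-03   3   2   1   1
-7.6838228129961278e-03   3   2   2   1
-3.3804793073607078e-02   3   2   2   2
 1.2030740871571844e-03   3   2   3   1
 9.2569853533254823e-03   3   2   3   2
 3.9007817005688472e-01   3   3   1   1
-1.7808807041482976e-02   3   3   2   1
 2.5544398399323737e-01   3   3   2   2
 4.3944944805651290e-03   3   3   3   1
-5.7697493682508094e-03   3   3   3   2
 3.3659087386233566e-01   3   3   3   3
 1.0001887129355114e-02   4   1   4   1
 8.8419567275327578e-03   4   2   4   1
 2.9120011114154874e-02   4   2   4   2
 1.0163886865203121e-02   4   3   4   1
 2.0254003406613565e-02   4   3   4   2
 4.3084292308021847e-02   4   3   4   3
 3.9586222931724308e-01   4   4   1   1
-6.1713875597996610e-03   4   4   2   1
 3.0850941255966507e-01   4   4   2   2
-3.5238763641962582e-03   4   4   3   1
-5.0604881715211208e-04   4   4   3   2
 2.8254669499771706e-01   4   4   3   3
 3.1294546903540249e-01   4   4   4   4
 1.0001887129355120e-02   5   1   5   1
 8.8419567275327630e-03   5   2   5   1
 2.9120011114154885e-02   5   2   5   2
 1.0163886865203127e-02   5   3   5   1
 2.0254003406613572e-02   5   3   5   2
 4.3084292308021868e-02   5   3   5   3
 1.6869136896862844e-02   5   4   5   4
 3.9586222931724324e-01   5   5   1   1
-6.1713875597996532e-03   5   5   2   1
 3.0850941255966519e-01   5   5   2   2
-3.5238763641962582e-03   5   5   3   1
-5.0604881715210265e-04   5   5   3   2
 2.8254669499771712e-01   5   5   3   3
 2.7920719524167692e-01   5   5   4   4
 3.1294546903540271e-01   5   5   5   5
-1.4606519849933181e-01   6   1   1   1
 3.3863408726079541e-02   6   1   2   1
 9.5663450240362838e-03   6   1   2   2
 1.3443738618493573e-02   6   1   3   1
-7.6755274391492670e-03   6   1   3   2
-6.3857780792543443e-03   6   1   3   3
-5.1034924313584475e-03   6   1   4   4
-5.1034924313584492e-03   6   1   5   5
 2.8554882911395622e-02   6   1   6   1
 1.6597739288366686e-01   6   2   1   1
 1.1102695453692628e-02   6   2   2   1
 1.5927069093418092e-01   6   2   2   2
-2.0087137994549257e-02   6   2   3   1
-2.6442898954771282e-02   6   2   3   2
 2.8835884199216070e-02   6   2   3   3
 3.7055112717475781e-02   6   2   4   4
 3.7055112717475802e-02   6   2   5   5
 1.0433692176093443e-02   6   2   6   1
 1.2296836738279515e-01   6   2   6   2
 2.2484458594593984e-02   6   3   1   1
-1.5677732840869523e-02   6   3   2   1
-4.4743685886326684e-02   6   3   2   2
 6.0629915824983926e-03   6   3   3   1
 3.6425194670225108e-03   6   3   3   2
 3.5932405110469308e-02   6   3   3   3
 6.9827975780034190e-04   6   3   4   4
 6.9827975780034233e-04   6   3   5   5
-8.9019047555986067e-03   6   3   6   1
-2.7825230521096627e-02   6   3   6   2
 2.7233189643338554e-02   6   3   6   3
-1.5295916472495041e-03   6   4   4   1
-1.2776312995656973e-02   6   4   4   2
-9.4197864974049916e-03   6   4   4   3
 1.2541239946111967e-02   6   4   6   4
-1.5295916472495045e-03   6   5   5   1
-1.2776312995656977e-02   6   5   5   2
-9.4197864974049934e-03   6   5   5   3
 1.2541239946111971e-02   6   5   6   5
 4.4877084456608723e-01   6   6   1   1
 1.6123475336811834e-02   6   6   2   1
 4.5576475658762283e-01   6   6   2   2
-2.3927123984283368e-02   6   6   3   1
-3.4067013664534858e-02   6   6   3   2
 2.5018237755537509e-01   6   6   3   3
 2.7817831951899707e-01   6   6   4   4
 2.7817831951899719e-01   6   6   5   5
 1.5097531941930089e-02   6   6   6   1
 1.5688341268224706e-01   6   6   6   2
-3.8766373442706954e-02   6   6   6   3
 4.3910898990309599e-01   6   6   6   6
-5.0478571988221148e+00   1   1   0   0
 1.7049712356583993e-01   2   1   0   0
-1.8038123091365024e+00   2   2   0   0
 1.6029154789290870e-01   3   1   0   0
 5.6938207825350765e-02   3   2   0   0
-1.1971184464529945e+00   3   3   0   0
-1.2204337533726757e+00   4   4   0   0
-1.2204337533726759e+00   5   5   0   0
 1.3803520390255591e-01   6   1   0   0
-4.5736206800327794e-01   6   2   0   0
 3.1519294265514211e-02   6   3   0   0
-1.0642804801112689e+00   6   6   0   0
 1.9844145408862499e+00   0   0   0   0
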