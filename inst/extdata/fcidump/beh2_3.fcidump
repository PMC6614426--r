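 &FCI NORB=7,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,1,
  ISYM=1,
 &END
 2.2747388400683071e+00   1   1   1   1
 2.1958339227253978e-01   2   1   1   1
 3.3212260681237067e-02   2   1   2   1
 4.7453278264144649e-01   2   2   1   1
 9.2756424115585431e-03   2   2   2   1
 3.2103339549043947e-01   2   2   2   2
 2.2108616138572018e-03   3   1   3   1
-3.4665617335080828e-03   3   2   3   1
 8.7703731350291511e-02   3   2   3   2
 2.3779963322113826e-01   3   3   1   1
 1.1649349861544303e-03   3   3   2   1
 2.5234274665190526e-01   3   3   2   2
 3.5592487144226653e-01   3   3   3   3
-1.2925394970812307e-01   4   1   1   1
-1.9611527793543485e-02   4   1   2   1
-5.3780511120180858e-03   4   1   2   2
-5.7514315199929463e-04   4   1   3   3
 1.1581200071056046e-02   4   1   4   1
-1.7151997405723368e-01   4   2   1   1
-5.4567559074225509e-03   4   2   2   1
-5.0668058768401018e-02   4   2   2   2
 7.1330022686662747e-02   4   2   3   3
 3.2297477824720666e-03   4   2   4   1
 8.6706782630047413e-02   4   2   4   2
 1.9736112382967783e-04   4   3   3   1
 1.1950607367661233e-01   4   3   3   2
 2.0943670454809524e-01   4   3   4   3
 2.7483194157310581e-01   4   4   1   1
 3.3001055924863380e-03   4   4   2   1
 2.6208838921925032e-01   4   4   2   2
 3.4812449031780252e-01   4   4   3   3
-1.8062001226320532e-03   4   4   4   1
 5.9240600632973886e-02   4   4   4   2
 3.4461288016084213e-01   4   4   4   4
 1.5623575695704403e-02   5   1   5   1
-1.7806187462992732e-02   5   2   5   1
 6.5196539250380117e-02   5   2   5   2
 3.8584826047127880e-03   5   3   5   3
 1.0486802425090022e-02   5   4   5   1
-3.7873275523943463e-02   5   4   5   2
 2.2066097552909027e-02   5   4   5   4
 5.6921931939765735e-01   5   5   1   1
 7.8314332859186382e-03   5   5   2   1
 3.5183090144201240e-01   5   5   2   2
 2.0771404186234282e-01   5   5   3   3
-4.4668230727464417e-03   5   5   4   1
-1.0326107383968340e-01   5   5   4   2
 2.2859936377723103e-01   5   5   4   4
 4.4985911173839266e-01   5   5   5   5
 1.5623575695704413e-02   6   1   6   1
-1.7806187462992749e-02   6   2   6   1
 6.5196539250380173e-02   6   2   6   2
 3.8584826047127910e-03   6   3   6   3
 1.0486802425090033e-02   6   4   6   1
-3.7873275523943498e-02   6   4   6   2
 2.2066097552909048e-02   6   4   6   4
 2.4249384289240516e-02   6   5   6   5
 5.6921931939765791e-01   6   6   1   1
 7.8314332859186434e-03   6   6   2   1
 3.5183090144201273e-01   6   6   2   2
 2.0771404186234299e-01   6   6   3   3
-4.4668230727464460e-03   6   6   4   1
-1.0326107383968348e-01   6   6   4   2
 2.2859936377723122e-01   6   6   4   4
 4.0136034315991226e-01   6   6   5   5
 4.4985911173839349e-01   6   6   6   6
-5.4979823246918014e-03   7   1   3   1
 8.6024713595395201e-03   7   1   3   2
-2.5783108800623596e-04   7   1   4   3
 1.3675164542138204e-02   7   1   7   1
 6.0170264526967603e-03   7   2   3   1
-6.3656625792184078e-03   7   2   3   2
 4.3427871610458642e-02   7   2   4   3
-1.4697106996974582e-02   7   2   7   1
 5.9221703973680540e-02   7   2   7   2
-1.4397301578658908e-01   7   3   1   1
-2.7259305230777024e-03   7   3   2   1
-4.5525577940263691e-02   7   3   2   2
 6.2020009611235605e-02   7   3   3   3
 1.6486474750737189e-03   7   3   4   1
 7.7463564514814398e-02   7   3   4   2
 5.4968585727767159e-02   7   3   4   4
-8.6142679626085267e-02   7   3   5   5
-8.6142679626085350e-02   7   3   6   6
 7.5503807793932412e-02   7   3   7   3
-4.0576860237625028e-03   7   4   3   1
 8.1095910071026192e-02   7   4   3   2
 1.0709923486352431e-01   7   4   4   3
 1.0100786638144869e-02   7   4   7   1
-1.0664915664303070e-02   7   4   7   2
 7.7133775178574671e-02   7   4   7   4
-8.8814601697411160e-03   7   5   5   3
 2.0705284784654922e-02   7   5   7   5
-8.8814601697411247e-03   7   6   6   3
 2.0705284784654939e-02   7   6   7   6
 5.1204265808175708e-01   7   7   1   1
 6.8324043243558064e-03   7   7   2   1
 3.3958854833908930e-01   7   7   2   2
 2.6190733593147758e-01   7   7   3   3
-3.9355399108539435e-03   7   7   4   1
-5.9765501010934807e-02   7   7   4   2
 2.6856354249992909e-01   7   7   4   4
 3.6568319278927369e-01   7   7   5   5
 3.6568319278927408e-01   7   7   6   6
-6.3806105233780969e-02   7   7   7   3
 3.8312383046727683e-01   7   7   7   7
-8.2099838405889152e+00   1   1   0   0
-2.3465546634023318e-01   2   1   0   0
-1.9256720745785649e+00   2   2   0   0
-1.4081887051200086e+00   3   3   0   0
 1.3590094340460881e-01   4   1   0   0
 3.5094250740270522e-01   4   2   0   0
-1.4415947197771859e+00   4   4   0   0
-1.9744619419165894e+00   5   5   0   0
-1.9744619419165912e+00   6   6   0   0
 3.0511353248010031e-01   7   3   0   0
-1.8591942677845734e+00   7   7   0   0
 1.4993354308918334e+00   0   0   0   0
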