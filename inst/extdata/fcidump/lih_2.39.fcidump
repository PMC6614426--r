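 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6594869400817478e+00   1   1   1   1
 9.7639269314086896e-02   2   1   1   1
 9.8365004888033170e-03   2   1   2   1
 2.9780613023147301e-01   2   2   1   1
-1.8633307762198326e-03   2   2   2   1
 4.3551563298851975e-01   2   2   2   2
-1.4253746701024786e-01   3   1   1   1
-1.0822889256566907e-02   3   1   2   1
-9.8655441717460535e-03   3   1   2   2
 2.2007029276895212e-02   3   1   3   1
-3.6746781634085131e-02   3   2   1   1
-2.4993961511983087e-03   3   2   2   1
 6.6311048838360628e-02   3   2   2   2
 4.3924147101489754e-04   3   2   3   1
 2.8361256334489771e-02   3   2   3   2
 3.8703664963488565e-01   3   3   1   1
 8.2644504837623093e-03   3   3   2   1
 2.1228969796535682e-01   3   3   2   2
 4.6527678592833010e-04   3   3   3   1
-1.7208524625417169e-02   3   3   3   2
 3.2149445849842423e-01   3   3   3   3
 9.7988482458205555e-03   4   1   4   1
-7.3079941385955456e-03   4   2   4   1
 2.0857419279742485e-02   4   2   4   2
 1.0437334703946590e-02   4   3   4   1
-2.1182940596095060e-02   4   3   4   2
 4.1371574002543897e-02   4   3   4   3
 3.9634516739411485e-01   4   4   1   1
 3.4907496137898111e-03   4   4   2   1
 2.3501480701754662e-01   4   4   2   2
-5.0750647342169284e-03   4   4   3   1
-1.8747990084249107e-02   4   4   3   2
 2.7745838276601265e-01   4   4   3   3
 3.1294546903540332e-01   4   4   4   4
 9.7988482458205572e-03   5   1   5   1
-7.3079941385955473e-03   5   2   5   1
 2.0857419279742488e-02   5   2   5   2
 1.0437334703946593e-02   5   3   5   1
-2.1182940596095066e-02   5   3   5   2
 4.1371574002543911e-02   5   3   5   3
 1.6869136896862886e-02   5   4   5   4
 3.9634516739411496e-01   5   5   1   1
 3.4907496137898146e-03   5   5   2   1
 2.3501480701754665e-01   5   5   2   2
-5.0750647342169405e-03   5   5   3   1
-1.8747990084249114e-02   5   5   3   2
 2.7745838276601276e-01   5   5   3   3
 2.7920719524167770e-01   5   5   4   4
 3.1294546903540355e-01   5   5   5   5
 6.6002590959756677e-02   6   1   1   1
 8.6801220863610036e-03   6   1   2   1
-6.9567059878709939e-03   6   1   2   2
-4.2619965249687261e-03   6   1   3   1
-2.9258746578824661e-03   6   1   3   2
 1.1512007162216615e-02   6   1   3   3
 1.6359731553076591e-03   6   1   4   4
 1.6359731553076595e-03   6   1   5   5
 1.0457674444646009e-02   6   1   6   1
 8.7110022380234603e-02   6   2   1   1
 9.3528438169668542e-04   6   2   2   1
-1.0348699912993700e-01   6   2   2   2
-4.7394956543729055e-03   6   2   3   1
-5.1609777651051250e-02   6   2   3   2
 1.6487368004491878e-02   6   2   3   3
 4.2784209903875881e-02   6   2   4   4
 4.2784209903875887e-02   6   2   5   5
-1.6317886694063785e-03   6   2   6   1
 1.3221647150791505e-01   6   2   6   2
 2.8120540320979940e-02   6   3   1   1
 2.1211168062108383e-03   6   3   2   1
-6.3633063547746588e-02   6   3   2   2
 3.8844236127463004e-03   6   3   3   1
-2.3817321422240398e-02   6   3   3   2
 3.7202816499012276e-02   6   3   3   3
 1.1521633635559272e-02   6   3   4   4
 1.1521633635559275e-02   6   3   5   5
 4.7659452299786201e-03   6   3   6   1
 4.3998245977866147e-02   6   3   6   2
 3.6490819851181432e-02   6   3   6   3
-5.4510183387331051e-03   6   4   4   1
 1.7542880179032810e-02   6   4   4   2
-1.0747286531360820e-02   6   4   4   3
 1.8491322530844161e-02   6   4   6   4
-5.4510183387331060e-03   6   5   5   1
 1.7542880179032813e-02   6   5   5   2
-1.0747286531360825e-02   6   5   5   3
 1.8491322530844165e-02   6   5   6   5
 3.4643959115871098e-01   6   6   1   1
-3.0491447429933385e-04   6   6   2   1
 4.0426467273786876e-01   6   6   2   2
-1.0096545158091934e-02   6   6   3   1
 5.1140830070567057e-02   6   6   3   2
 2.3974279166100437e-01   6   6   3   3
 2.5405463667136496e-01   6   6   4   4
 2.5405463667136502e-01   6   6   5   5
-5.3166315127961957e-03   6   6   6   1
-8.1856505720458619e-02   6   6   6   2
-4.7372168243298894e-02   6   6   6   3
 3.9655315396383889e-01   6   6   6   6
-4.6187371833256528e+00   1   1   0   0
-9.5775938541248426e-02   2   1   0   0
-1.2389744388733828e+00   2   2   0   0
 1.5976915920094470e-01   3   1   0   0
-3.6403748052463727e-03   3   2   0   0
-1.0811709233951361e+00   3   3   0   0
-1.0742880696265451e+00   4   4   0   0
-1.0742880696265455e+00   5   5   0   0
-5.1153894607147414e-02   6   1   0   0
-6.2052923563479634e-02   6   2   0   0
 1.5153272268888063e-02   6   3   0   0
-1.0213859634282281e+00   6   6   0   0
 6.6423917686569034e-01   0   0   0   0
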