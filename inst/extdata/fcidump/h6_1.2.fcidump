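 &FCI NORB=6,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 3.8727443670964773e-01   1   1   1   1
 1.2855473784855173e-01   2   1   2   1
 3.1014653785812196e-01   2   2   1   1
 3.4553018600734359e-01   2   2   2   2
 7.4158847785289347e-02   3   1   1   1
-3.3841037207277859e-02   3   1   2   2
 1.0411302795517280e-01   3   1   3   1
-9.8562827167397116e-02   3   2   2   1
 1.2196942719333831e-01   3   2   3   2
 3.3156333115546849e-01   3   3   1   1
 3.1192109198412238e-01   3   3   2   2
 2.2245916084762264e-02   3   3   3   1
 3.3647476251879260e-01   3   3   3   3
-4.8106922418015861e-02   4   1   2   1
-1.7042754778124492e-02   4   1   3   2
 8.1287042440880475e-02   4   1   4   1
-7.1585002284655960e-02   4   2   1   1
-7.2728134914511605e-03   4   2   2   2
-5.8220055287531984e-02   4   2   3   1
-9.9190382222795101e-04   4   2   3   3
 8.4431601015246674e-02   4   2   4   2
-7.8134192947197326e-02   4   3   2   1
 7.5987901579869122e-02   4   3   3   2
 1.0695485337062789e-02   4   3   4   1
 1.0529641054103893e-01   4   3   4   3
 3.3582478826075629e-01   4   4   1   1
 3.1497361913444810e-01   4   4   2   2
 2.2499201826352108e-02   4   4   3   1
 3.3264367388121857e-01   4   4   3   3
-8.7019355365290357e-03   4   4   4   2
 3.4358821748746782e-01   4   4   4   4
 6.3757030935262396e-03   5   1   1   1
 3.4646763954239372e-02   5   1   2   2
-3.0862633115479429e-02   5   1   3   1
-1.7296382168773747e-02   5   1   3   3
-3.1544162587045801e-02   5   1   4   2
-1.1212662785838105e-02   5   1   4   4
 5.5559345367865290e-02   5   1   5   1
 3.9854437738076884e-02   5   2   2   1
 1.3613627049301814e-03   5   2   3   2
-5.2872333633838857e-02   5   2   4   1
 4.0252783063488722e-02   5   2   4   3
 9.0682117327500367e-02   5   2   5   2
-7.4064069048819792e-02   5   3   1   1
-9.1273009090408717e-03   5   3   2   2
-5.9812635266277510e-02   5   3   3   1
-9.0688907404451527e-03   5   3   3   3
 8.0351031730179837e-02   5   3   4   2
-6.0003222318513868e-03   5   3   4   4
-2.7047393039320120e-02   5   3   5   1
 8.5056410785387254e-02   5   3   5   3
-1.0089093879469152e-01   5   4   2   1
 1.1819211632924892e-01   5   4   3   2
-1.0587426332751306e-02   5   4   4   1
 7.7884500955625352e-02   5   4   4   3
-6.6380929154363438e-06   5   4   5   2
 1.2550016875272102e-01   5   4   5   4
 3.2289623556399821e-01   5   5   1   1
 3.5233965619706981e-01   5   5   2   2
-2.7643297432275733e-02   5   5   3   1
 3.2371584522789398e-01   5   5   3   3
-9.9875546135940012e-03   5   5   4   2
 3.2980893774349007e-01   5   5   4   4
 3.3689097016108303e-02   5   5   5   1
-1.1550131379592304e-02   5   5   5   3
 3.7292829113039655e-01   5   5   5   5
-1.1851540001768582e-03   6   1   2   1
-2.3974741440062695e-02   6   1   3   2
 2.9924825466962568e-02   6   1   4   1
 4.7143415937845462e-02   6   1   4   3
 3.8401813633431807e-02   6   1   5   2
-2.2145331820807888e-02   6   1   5   4
 7.2742443264671414e-02   6   1   6   1
 7.5479331708379130e-03   6   2   1   1
 3.5414343685569047e-02   6   2   2   2
-2.9813931423019267e-02   6   2   3   1
-1.1873923151000314e-02   6   2   3   3
-2.8223739985552308e-02   6   2   4   2
-1.4001297472642026e-02   6   2   4   4
 5.2408079502106283e-02   6   2   5   1
-3.0269213231722370e-02   6   2   5   3
 3.5436652720665325e-02   6   2   5   5
 5.4409797486960308e-02   6   2   6   2
-4.8673613694857884e-02   6   3   2   1
-1.1698864942485895e-02   6   3   3   2
 7.7525231983231052e-02   6   3   4   1
 1.1534104190639603e-02   6   3   4   3
-5.3406515907047827e-02   6   3   5   2
-1.3008558579955039e-02   6   3   5   4
 2.8784684701404203e-02   6   3   6   1
 8.1651057676449049e-02   6   3   6   3
 7.6986353574224703e-02   6   4   1   1
-2.8921336621520976e-02   6   4   2   2
 1.0235347859289748e-01   6   4   3   1
 2.3966983403994762e-02   6   4   3   3
-6.0720858621483548e-02   6   4   4   2
 2.5150959618121915e-02   6   4   4   4
-2.9080233340835374e-02   6   4   5   1
-6.2287838598423101e-02   6   4   5   3
-3.0370927160471104e-02   6   4   5   5
-2.9695026719503467e-02   6   4   6   2
 1.1040791459517674e-01   6   4   6   4
 1.3249697230411123e-01   6   5   2   1
-1.0410164471085599e-01   6   5   3   2
-4.8751199299812510e-02   6   5   4   1
-8.3345344147369035e-02   6   5   4   3
 4.1312540759820479e-02   6   5   5   2
-1.0875862110643747e-01   6   5   5   4
-1.3964027371021186e-03   6   5   6   1
-5.2763662408702443e-02   6   5   6   3
 1.4753508443942262e-01   6   5   6   5
 4.0933960582439094e-01   6   6   1   1
 3.2925854237889024e-01   6   6   2   2
 7.8458471174627592e-02   6   6   3   1
 3.5355326360404621e-01   6   6   3   3
-7.6882037962154814e-02   6   6   4   2
 3.6072396696920495e-01   6   6   4   4
 7.0890065797100639e-03   6   6   5   1
-8.1491662849691934e-02   6   6   5   3
 3.5008256631415996e-01   6   6   5   5
 8.9469267537396306e-03   6   6   6   2
 8.5952605979347979e-02   6   6   6   4
 4.5202705233512674e-01   6   6   6   6
-2.0035249284505090e+00   1   1   0   0
-1.8044972600370208e+00   2   2   0   0
-1.2728551663780538e-01   3   1   0   0
-1.7008863579542701e+00   3   3   0   0
 1.8030760488249103e-01   4   2   0   0
-1.5444877731921798e+00   4   4   0   0
-6.1034664178283550e-02   5   1   0   0
 1.4595036026101513e-01   5   3   0   0
-1.3362111786710711e+00   5   5   0   0
-3.9646382664439248e-02   6   2   0   0
-1.3082881104739585e-01   6   4   0   0
-1.2753721663393003e+00   6   6   0   0
 3.8365347790467501e+00   0   0   0   0
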