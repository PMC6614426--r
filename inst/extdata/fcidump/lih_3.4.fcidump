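 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6601523799545732e+00   1   1   1   1
 1.0866170052067547e-01   2   1   1   1
 1.1397263559735797e-02   2   1   2   1
 2.5984372659947985e-01   2   2   1   1
 8.4540488416190993e-04   2   2   2   1
 3.8219391709362682e-01   2   2   2   2
 1.4208583463106345e-01   3   1   1   1
 1.3262104830826089e-02   3   1   2   1
 6.0548090931035461e-03   3   1   2   2
 2.0315740798298624e-02   3   1   3   1
 8.8785224708355134e-02   3   2   1   1
 2.9561942561150576e-03   3   2   2   1
-1.0762401581911259e-01   3   2   2   2
 1.8867965174054471e-03   3   2   3   1
 9.7605073018169383e-02   3   2   3   2
 3.4420324887414494e-01   3   3   1   1
 6.0147901706901104e-03   3   3   2   1
 2.5183299529330339e-01   3   3   2   2
 2.1991047171449813e-03   3   3   3   1
-4.1770369686585651e-03   3   3   3   2
 2.7986519148054506e-01   3   3   3   3
 9.7737229952135161e-03   4   1   4   1
-8.1675847956567526e-03   4   2   4   1
 2.3315850066258657e-02   4   2   4   2
-1.0500126357904586e-02   4   3   4   1
 2.6531842714439893e-02   4   3   4   2
 3.9175792471535714e-02   4   3   4   3
 3.9635578953110762e-01   4   4   1   1
 3.7534640933996385e-03   4   4   2   1
 2.0665364749748025e-01   4   4   2   2
 4.9611209694921709e-03   4   4   3   1
 5.0677945722974259e-02   4   4   3   2
 2.5297960734225466e-01   4   4   3   3
 3.1294546903540293e-01   4   4   4   4
 9.7737229952135161e-03   5   1   5   1
-8.1675847956567509e-03   5   2   5   1
 2.3315850066258650e-02   5   2   5   2
-1.0500126357904583e-02   5   3   5   1
 2.6531842714439886e-02   5   3   5   2
 3.9175792471535700e-02   5   3   5   3
 1.6869136896862848e-02   5   4   5   4
 3.9635578953110756e-01   5   5   1   1
 3.7534640933996337e-03   5   5   2   1
 2.0665364749748022e-01   5   5   2   2
 4.9611209694921691e-03   5   5   3   1
 5.0677945722974280e-02   5   5   3   2
 2.5297960734225466e-01   5   5   3   3
 2.7920719524167714e-01   5   5   4   4
 3.1294546903540282e-01   5   5   5   5
 3.5568137937714281e-02   6   1   1   1
 5.6338151385023974e-03   6   1   2   1
-5.3526924128816976e-03   6   1   2   2
 1.0959524559730196e-03   6   1   3   1
 3.1652305220840290e-03   6   1   3   2
 8.0496896231909178e-03   6   1   3   3
 9.1638431022797678e-04   6   1   4   4
 9.1638431022797668e-04   6   1   5   5
 8.8918215357470520e-03   6   1   6   1
 8.3107338147156457e-02   6   2   1   1
 7.6887255945130030e-06   6   2   2   1
-7.6350005402359505e-02   6   2   2   2
 4.7640884248777325e-03   6   2   3   1
 8.2361809336024633e-02   6   2   3   2
-2.3813131022976254e-02   6   2   3   3
 4.6906382374654096e-02   6   2   4   4
 4.6906382374654096e-02   6   2   5   5
-5.1991981036685750e-03   6   2   6   1
 9.9250243716908063e-02   6   2   6   2
-5.0701109654148077e-02   6   3   1   1
-2.4052294403157318e-03   6   3   2   1
 8.7970484645114366e-02   6   3   2   2
 3.2590361011411322e-03   6   3   3   1
-7.0457784534765047e-02   6   3   3   2
-1.4710151086182550e-02   6   3   3   3
-2.7372180970688186e-02   6   3   4   4
-2.7372180970688179e-02   6   3   5   5
-7.9182669480062674e-03   6   3   6   1
-4.3743409899794874e-02   6   3   6   2
 7.1582192672758310e-02   6   3   6   3
-2.9503383505713370e-03   6   4   4   1
 1.1605521148837623e-02   6   4   4   2
 3.8379459899749919e-03   6   4   4   3
 1.5825031708889985e-02   6   4   6   4
-2.9503383505713365e-03   6   5   5   1
 1.1605521148837622e-02   6   5   5   2
 3.8379459899749910e-03   6   5   5   3
 1.5825031708889981e-02   6   5   6   5
 3.5172970931247255e-01   6   6   1   1
 1.9167414342182714e-03   6   6   2   1
 3.0326115174073137e-01   6   6   2   2
 6.7368511902591490e-03   6   6   3   1
-2.7019921810493265e-02   6   6   3   2
 2.6016092364961785e-01   6   6   3   3
 2.5392376552628682e-01   6   6   4   4
 2.5392376552628676e-01   6   6   5   5
-4.2569204637435531e-03   6   6   6   1
-2.1138845524632357e-03   6   6   6   2
 2.4165867097391290e-02   6   6   6   3
 3.0586509153794655e-01   6   6   6   6
-4.5533736992422105e+00   1   1   0   0
-1.0950710539976645e-01   2   1   0   0
-1.0445803445998674e+00   2   2   0   0
-1.5123925855992640e-01   3   1   0   0
-5.6684328709265611e-02   3   2   0   0
-1.0246148452002246e+00   3   3   0   0
-1.0243863599808698e+00   4   4   0   0
-1.0243863599808696e+00   5   5   0   0
-2.4855064380588893e-02   6   1   0   0
-8.4230855736644197e-02   6   2   0   0
 8.9190118054536111e-03   6   3   0   0
-1.0084235867373170e+00   6   6   0   0
 4.6692106844382353e-01   0   0   0   0
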