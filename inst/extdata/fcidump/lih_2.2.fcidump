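 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6593249133327030e+00   1   1   1   1
 9.8051259045312381e-02   2   1   1   1
 1.0019372242818491e-02   2   1   2   1
 3.1029740761908731e-01   2   2   1   1
-2.5402137189508593e-03   2   2   2   1
 4.4735229189368153e-01   2   2   2   2
 1.4196158005333584e-01   3   1   1   1
 1.0636759943710215e-02   3   1   2   1
 1.0892854863787455e-02   3   1   2   2
 2.2036255774600992e-02   3   1   3   1
 2.9836626303683594e-02   3   2   1   1
 2.5380066702368437e-03   3   2   2   1
-6.1056811139648039e-02   3   2   2   2
 2.6408653421731119e-04   3   2   3   1
 2.2905546596503665e-02   3   2   3   2
 3.9028352965524965e-01   3   3   1   1
 8.7011350970297684e-03   3   3   2   1
 2.1264613808855992e-01   3   3   2   2
-8.1028283732261115e-04   3   3   3   1
 1.5225207093481975e-02   3   3   3   2
 3.2701185157446999e-01   3   3   3   3
 9.8049385698948874e-03   4   1   4   1
-7.2663678423865348e-03   4   2   4   1
 2.1087617993770156e-02   4   2   4   2
-1.0395539383241354e-02   4   3   4   1
 2.0502683621297455e-02   4   3   4   2
 4.1387606227893607e-02   4   3   4   3
 3.9634213475152419e-01   4   4   1   1
 3.5647995109362668e-03   4   4   2   1
 2.4259396121563398e-01   4   4   2   2
 5.0692637946724425e-03   4   4   3   1
 1.4754498445920333e-02   4   4   3   2
 2.7918438980863880e-01   4   4   3   3
 3.1294546903540338e-01   4   4   4   4
 9.8049385698948874e-03   5   1   5   1
-7.2663678423865322e-03   5   2   5   1
 2.1087617993770152e-02   5   2   5   2
-1.0395539383241352e-02   5   3   5   1
 2.0502683621297459e-02   5   3   5   2
 4.1387606227893593e-02   5   3   5   3
 1.6869136896862882e-02   5   4   5   4
 3.9634213475152408e-01   5   5   1   1
 3.5647995109362599e-03   5   5   2   1
 2.4259396121563392e-01   5   5   2   2
 5.0692637946724399e-03   5   5   3   1
 1.4754498445920366e-02   5   5   3   2
 2.7918438980863880e-01   5   5   3   3
 2.7920719524167759e-01   5   5   4   4
 3.1294546903540327e-01   5   5   5   5
 6.8318660128653952e-02   6   1   1   1
 9.0661342542581909e-03   6   1   2   1
-7.3107619794487320e-03   6   1   2   2
 4.4479590342644624e-03   6   1   3   1
 2.7886696991125306e-03   6   1   3   2
 1.1718194272651156e-02   6   1   3   3
 1.6039671157602390e-03   6   1   4   4
 1.6039671157602386e-03   6   1   5   5
 1.0749578050254999e-02   6   1   6   1
 8.1693085402401291e-02   6   2   1   1
 1.3667108187634216e-03   6   2   2   1
-1.0683876696297008e-01   6   2   2   2
 4.2980638883502852e-03   6   2   3   1
 4.6031691099075997e-02   6   2   3   2
 1.8348053629488260e-02   6   2   3   3
 3.8468833752129061e-02   6   2   4   4
 3.8468833752129054e-02   6   2   5   5
-1.0934984193979615e-03   6   2   6   1
 1.3119257962476435e-01   6   2   6   2
-2.4400768027864235e-02   6   3   1   1
-2.2032573259490366e-03   6   3   2   1
 5.9156449057727316e-02   6   3   2   2
 3.9551435405815695e-03   6   3   3   1
-1.8836953535975316e-02   6   3   3   2
-3.6844449366669120e-02   6   3   3   3
-8.8245964994267349e-03   6   3   4   4
-8.8245964994267331e-03   6   3   5   5
-4.5222178920185279e-03   6   3   6   1
-4.0427288517427676e-02   6   3   6   2
 3.2311189935059804e-02   6   3   6   3
-5.7608344393909943e-03   6   4   4   1
 1.8239439793321797e-02   6   4   4   2
 1.1682201074723259e-02   6   4   4   3
 1.9062460962674558e-02   6   4   6   4
-5.7608344393909926e-03   6   5   5   1
 1.8239439793321793e-02   6   5   5   2
 1.1682201074723253e-02   6   5   5   3
 1.9062460962674558e-02   6   5   6   5
 3.5082698871371637e-01   6   6   1   1
-6.7610413301423468e-04   6   6   2   1
 4.1865941172233401e-01   6   6   2   2
 1.0581093989277778e-02   6   6   3   1
-4.9757944185870553e-02   6   6   3   2
 2.3875471684393884e-01   6   6   3   3
 2.5732772525182435e-01   6   6   4   4
 2.5732772525182435e-01   6   6   5   5
-5.1885414259897284e-03   6   6   6   1
-9.4440492634646572e-02   6   6   6   2
 4.6793728090961308e-02   6   6   6   3
 4.1361954701407355e-01   6   6   6   6
-4.6377471382772519e+00   1   1   0   0
-9.5511045326404725e-02   2   1   0   0
-1.2909667390933763e+00   2   2   0   0
-1.6120928311065882e-01   3   1   0   0
 1.2020318475812895e-02   3   2   0   0
-1.0907373118322645e+00   3   3   0   0
-1.0869314536147237e+00   4   4   0   0
-1.0869314536147234e+00   5   5   0   0
-5.2330425351053617e-02   6   1   0   0
-4.7481269587839318e-02   6   2   0   0
-1.9031711926233884e-02   6   3   0   0
-1.0162519873111688e+00   6   6   0   0
 7.2160528759499987e-01   0   0   0   0
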