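 &FCI NORB=6,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 4.8494109671217567e-01   1   1   1   1
 1.3691911764705858e-01   2   1   2   1
 3.9491882106642473e-01   2   2   1   1
 4.2108216374970697e-01   2   2   2   2
 8.7234806618906924e-02   3   1   1   1
-2.0413977752262492e-02   3   1   2   2
 1.0035948184190570e-01   3   1   3   1
-1.0404901143744319e-01   3   2   2   1
 1.3221270189658740e-01   3   2   3   2
 4.0750581877703873e-01   3   3   1   1
 3.9240661889748779e-01   3   3   2   2
 2.0585769708398458e-02   3   3   3   1
 4.1564416198473431e-01   3   3   3   3
 5.5208744788330828e-02   4   1   2   1
 1.2037607886670392e-02   4   1   3   2
 7.7796302659888281e-02   4   1   4   1
 9.1147883622173728e-02   4   2   1   1
 2.1506217331664006e-02   4   2   2   2
 6.2712475995521086e-02   4   2   3   1
 5.5087043990863426e-03   4   2   3   3
 9.0038207710750884e-02   4   2   4   2
 8.9663215307606250e-02   4   3   2   1
-9.4753153859794978e-02   4   3   3   2
 9.5907479952882357e-03   4   3   4   1
 1.1360618216859432e-01   4   3   4   3
 4.1884050189864269e-01   4   4   1   1
 4.0017661906935947e-01   4   4   2   2
 2.3052621361049578e-02   4   4   3   1
 4.0962608684655771e-01   4   4   3   3
 2.3815105895698560e-02   4   4   4   2
 4.2873226856410862e-01   4   4   4   4
-1.6674584449873802e-03   5   1   1   1
-3.8467000501903471e-02   5   1   2   2
 3.6537943736732061e-02   5   1   3   1
 1.4660507563760545e-02   5   1   3   3
-2.3747075072477752e-02   5   1   4   2
 5.1642532786089484e-04   5   1   4   4
 5.6611891282515030e-02   5   1   5   1
-4.9320013892654259e-02   5   2   2   1
 6.1879454571438066e-03   5   2   3   2
-5.2371993031616708e-02   5   2   4   1
 2.5933221898172338e-02   5   2   4   3
 8.1999875176446538e-02   5   2   5   2
 9.5305531911602542e-02   5   3   1   1
 2.2779395252430282e-02   5   3   2   2
 6.6856467883395304e-02   5   3   3   1
 2.0247541176776917e-02   5   3   3   3
 8.0829389061533724e-02   5   3   4   2
 1.8894531127785882e-02   5   3   4   4
-1.1527802197111529e-02   5   3   5   1
 8.8977477355240794e-02   5   3   5   3
-1.0991426234159667e-01   5   4   2   1
 1.2295305669566589e-01   5   4   3   2
-4.1760643445361229e-03   5   4   4   1
-9.4370612164713735e-02   5   4   4   3
 1.4774998821323018e-02   5   4   5   2
 1.3388999514508976e-01   5   4   5   4
 4.2613568041581468e-01   5   5   1   1
 4.3298628430342551e-01   5   5   2   2
-9.3009005254633399e-04   5   5   3   1
 4.1415276356944103e-01   5   5   3   3
 3.4877414505988739e-02   5   5   4   2
 4.2705425128768226e-01   5   5   4   4
-3.4603744061905396e-02   5   5   5   1
 3.7027839623318397e-02   5   5   5   3
 4.7168399512477222e-01   5   5   5   5
 2.7210765120409697e-03   6   1   2   1
 2.5336334461283021e-02   6   1   3   2
 2.9716753448060927e-02   6   1   4   1
 3.3220159698274736e-02   6   1   4   3
 2.9231255611941401e-02   6   1   5   2
 2.1822172221823331e-02   6   1   5   4
 6.6070717183606256e-02   6   1   6   1
-4.3240524971359696e-03   6   2   1   1
-3.8843075770190971e-02   6   2   2   2
 3.3522162377901246e-02   6   2   3   1
 4.5109021419996896e-03   6   2   3   3
-1.7065532706465762e-02   6   2   4   2
 5.8827557582166543e-03   6   2   4   4
 4.8383665645734514e-02   6   2   5   1
-1.8336297380094457e-02   6   2   5   3
-3.7956912576610817e-02   6   2   5   5
 5.1355650462168022e-02   6   2   6   2
 5.4002862087512038e-02   6   3   2   1
 3.7813790206206546e-03   6   3   3   2
 6.9540859270928373e-02   6   3   4   1
 1.1293317316400067e-02   6   3   4   3
-5.0672995789979858e-02   6   3   5   2
 1.6326004939630349e-03   6   3   5   4
 2.7848053749959530e-02   6   3   6   1
 7.5035128565817455e-02   6   3   6   3
 9.0868482671994474e-02   6   4   1   1
-1.0958804341939181e-02   6   4   2   2
 9.5646689915666799e-02   6   4   3   1
 2.4929394971366710e-02   6   4   3   3
 6.4316133909129242e-02   6   4   4   2
 2.8576566983183053e-02   6   4   4   4
 3.3553676225521772e-02   6   4   5   1
 6.8165254386523197e-02   6   4   5   3
-4.1438131144602109e-03   6   4   5   5
 3.3961091506060241e-02   6   4   6   2
 1.0690980108568814e-01   6   4   6   4
 1.4006892588544786e-01   6   5   2   1
-1.0971815553974756e-01   6   5   3   2
 5.6255346309446626e-02   6   5   4   1
 9.5756098590182512e-02   6   5   4   3
-5.2178389987270229e-02   6   5   5   2
-1.1882678791615298e-01   6   5   5   4
 3.3039881707961909e-03   6   5   6   1
 6.1229301745461297e-02   6   5   6   3
 1.6314730368827499e-01   6   5   6   5
 5.2595564231498437e-01   6   6   1   1
 4.3040570567863912e-01   6   6   2   2
 9.6320102447477365e-02   6   6   3   1
 4.4756037124609316e-01   6   6   3   3
 1.0301189407385079e-01   6   6   4   2
 4.6485546966466829e-01   6   6   4   4
-2.2221545310441931e-03   6   6   5   1
 1.1107845174930969e-01   6   6   5   3
 4.7932511017615576e-01   6   6   5   5
-5.7680340822535642e-03   6   6   6   2
 1.0933302460271668e-01   6   6   6   4
 6.1322465363371759e-01   6   6   6   6
-2.6551443290781180e+00   1   1   0   0
-2.3495308468207079e+00   2   2   0   0
-1.7104163225688032e-01   3   1   0   0
-2.1210369655878880e+00   3   3   0   0
-2.5436380245669937e-01   4   2   0   0
-1.8230738322126738e+00   4   4   0   0
 6.6816898287922824e-02   5   1   0   0
-2.1369150634981179e-01   5   3   0   0
-1.3957830839528951e+00   5   5   0   0
 4.4971832012732561e-02   6   2   0   0
-1.8573360854204560e-01   6   4   0   0
-9.8322849550460500e-01   6   6   0   0
 5.7548021685701256e+00   0   0   0   0
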