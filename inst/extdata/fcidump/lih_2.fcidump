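 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6591519811559985e+00   1   1   1   1
 1.0011817579078255e-01   2   1   1   1
 1.0535923495944736e-02   2   1   2   1
 3.2593114459624373e-01   2   2   1   1
-3.4221113654260699e-03   2   2   2   1
 4.6027757191531443e-01   2   2   2   2
-1.4111711450240128e-01   3   1   1   1
-1.0604909902905033e-02   3   1   2   1
-1.2202576197507541e-02   3   1   2   2
 2.1988889675560144e-02   3   1   3   1
-2.3499391122056030e-02   3   2   1   1
-2.6664269168450894e-03   3   2   2   1
 5.6319025491640792e-02   3   2   2   2
 9.7052656425552009e-05   3   2   3   1
 1.8620587509504141e-02   3   2   3   2
 3.9277086710529585e-01   3   3   1   1
 9.2698016155031530e-03   3   3   2   1
 2.1483545327215334e-01   3   3   2   2
 1.1538377856323031e-03   3   3   3   1
-1.2749714958786674e-02   3   3   3   2
 3.3166320028972324e-01   3   3   3   3
 9.8107742549485774e-03   4   1   4   1
-7.2813691250224813e-03   4   2   4   1
 2.1616980728823308e-02   4   2   4   2
 1.0346068847974892e-02   4   3   4   1
-1.9938188868022916e-02   4   3   4   2
 4.1340310656365002e-02   4   3   4   3
 3.9633804964037639e-01   4   4   1   1
 3.7217750014154256e-03   4   4   2   1
 2.5125325621466960e-01   4   4   2   2
-5.0524937645129511e-03   4   4   3   1
-1.1183242747041406e-02   4   4   3   2
 2.8047756411998509e-01   4   4   3   3
 3.1294546903540327e-01   4   4   4   4
 9.8107742549485896e-03   5   1   5   1
-7.2813691250224908e-03   5   2   5   1
 2.1616980728823332e-02   5   2   5   2
 1.0346068847974900e-02   5   3   5   1
-1.9938188868022937e-02   5   3   5   2
 4.1340310656365065e-02   5   3   5   3
 1.6869136896862900e-02   5   4   5   4
 3.9633804964037689e-01   5   5   1   1
 3.7217750014154343e-03   5   5   2   1
 2.5125325621466987e-01   5   5   2   2
-5.0524937645129537e-03   5   5   3   1
-1.1183242747041397e-02   5   5   3   2
 2.8047756411998542e-01   5   5   3   3
 2.7920719524167786e-01   5   5   4   4
 3.1294546903540404e-01   5   5   5   5
-6.8342401375709544e-02   6   1   1   1
-9.3842291636658404e-03   6   1   2   1
 7.5885691355657026e-03   6   1   2   2
 4.3320508715156952e-03   6   1   3   1
 2.5905002515682349e-03   6   1   3   2
-1.1734038307253091e-02   6   1   3   3
-1.4604830236187008e-03   6   1   4   4
-1.4604830236187025e-03   6   1   5   5
 1.0772599437720635e-02   6   1   6   1
-7.3177584680748170e-02   6   2   1   1
-2.0517339358212200e-03   6   2   2   1
 1.1141497406063978e-01   6   2   2   2
 3.5672858433912452e-03   6   2   3   1
 4.1200653061171183e-02   6   2   3   2
-1.8379214678108276e-02   6   2   3   3
-3.2699057472148893e-02   6   2   4   4
-3.2699057472148935e-02   6   2   5   5
-5.6474637930929066e-04   6   2   6   1
 1.2903418440764589e-01   6   2   6   2
-2.1268339249056401e-02   6   3   1   1
-2.4268647297230619e-03   6   3   2   1
 5.5471737901687683e-02   6   3   2   2
-4.0596809372405252e-03   6   3   3   1
 1.4819752695294059e-02   6   3   3   2
-3.6349288756176067e-02   6   3   3   3
-6.3236455717913236e-03   6   3   4   4
-6.3236455717913306e-03   6   3   5   5
 4.3894139427461155e-03   6   3   6   1
 3.7005652426165776e-02   6   3   6   2
 2.9234838357471864e-02   6   3   6   3
 6.0121349089259455e-03   6   4   4   1
-1.8875002369904824e-02   6   4   4   2
 1.2527473532846400e-02   6   4   4   3
 1.9548329056339912e-02   6   4   6   4
 6.0121349089259516e-03   6   5   5   1
-1.8875002369904845e-02   6   5   5   2
 1.2527473532846417e-02   6   5   5   3
 1.9548329056339932e-02   6   5   6   5
 3.5575970625092546e-01   6   6   1   1
-1.1707071805221387e-03   6   6   2   1
 4.3238466986196972e-01   6   6   2   2
-1.0990390045546711e-02   6   6   3   1
 4.7857697629725068e-02   6   6   3   2
 2.3897830173719006e-01   6   6   3   3
 2.6117048522348940e-01   6   6   4   4
 2.6117048522348973e-01   6   6   5   5
 4.8742536330120111e-03   6   6   6   1
 1.0756270275906432e-01   6   6   6   2
 4.5922312954082299e-02   6   6   6   3
 4.3006286899762636e-01   6   6   6   6
-4.6616662373814535e+00   1   1   0   0
-9.6696064424400818e-02   2   1   0   0
-1.3517106088610669e+00   2   2   0   0
 1.6285583998120778e-01   3   1   0   0
-1.9925153154762360e-02   3   2   0   0
-1.1013241447372215e+00   3   3   0   0
-1.1016492292022231e+00   4   4   0   0
-1.1016492292022244e+00   5   5   0   0
 5.1113529167470341e-02   6   1   0   0
 2.5555966132053388e-02   6   2   0   0
-2.2874093375116766e-02   6   3   0   0
-1.0038368141135643e+00   6   6   0   0
 7.9376581635449994e-01   0   0   0   0
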