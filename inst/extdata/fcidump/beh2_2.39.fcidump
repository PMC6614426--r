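 &FCI NORB=7,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,1,
  ISYM=1,
 &END
 2.2738766736624414e+00   1   1   1   1
 1.9293394474871176e-01   2   1   1   1
 2.5557684005142738e-02   2   1   2   1
 4.2800525235562237e-01   2   2   1   1
 6.3149163016429947e-03   2   2   2   1
 3.1829478618437790e-01   2   2   2   2
 3.7948450281265391e-03   3   1   3   1
-6.2476886300752476e-03   3   2   3   1
 1.2980797487561646e-01   3   2   3   2
 3.1842184155484937e-01   3   3   1   1
 1.7931574386227651e-03   3   3   2   1
 3.1243251035237452e-01   3   3   2   2
 3.4839168660860170e-01   3   3   3   3
-1.7148884880621668e-01   4   1   1   1
-2.2861829650833658e-02   4   1   2   1
-5.4623855494664959e-03   4   1   2   2
-1.4863936088627110e-03   4   1   3   3
 2.0455615426287373e-02   4   1   4   1
-1.7717169831042193e-01   4   2   1   1
-5.5590245222259214e-03   4   2   2   1
-1.5078644469182037e-02   4   2   2   2
 4.8100765899264798e-02   4   2   3   3
 4.9208886278830095e-03   4   2   4   1
 1.0062856962898148e-01   4   2   4   2
 1.1801674296101185e-03   4   3   3   1
 1.0420134677993312e-01   4   3   3   2
 1.2841837515164051e-01   4   3   4   3
 3.7077425048664575e-01   4   4   1   1
 5.1612540707279718e-03   4   4   2   1
 3.1619710978500226e-01   4   4   2   2
 3.3847176775481586e-01   4   4   3   3
-4.3310625093300192e-03   4   4   4   1
 3.2405426792628124e-02   4   4   4   2
 3.4170403711348812e-01   4   4   4   4
 1.5659629300274879e-02   5   1   5   1
-1.5671735807550043e-02   5   2   5   1
 5.1057654805849166e-02   5   2   5   2
 7.4123177513833053e-03   5   3   5   3
 1.3894127368647445e-02   5   4   5   1
-4.3703005206307696e-02   5   4   5   2
 3.7878689637428020e-02   5   4   5   4
 5.6920747823419204e-01   5   5   1   1
 6.9901258293051426e-03   5   5   2   1
 3.2910217910520606e-01   5   5   2   2
 2.6557722755975044e-01   5   5   3   3
-5.8151104785149847e-03   5   5   4   1
-1.0094351531812541e-01   5   5   4   2
 2.9175161938543626e-01   5   5   4   4
 4.4985911173839160e-01   5   5   5   5
 1.5659629300274890e-02   6   1   6   1
-1.5671735807550054e-02   6   2   6   1
 5.1057654805849201e-02   6   2   6   2
 7.4123177513833096e-03   6   3   6   3
 1.3894127368647450e-02   6   4   6   1
-4.3703005206307710e-02   6   4   6   2
 3.7878689637428034e-02   6   4   6   4
 2.4249384289240360e-02   6   5   6   5
 5.6920747823419227e-01   6   6   1   1
 6.9901258293051270e-03   6   6   2   1
 3.2910217910520623e-01   6   6   2   2
 2.6557722755975055e-01   6   6   3   3
-5.8151104785149838e-03   6   6   4   1
-1.0094351531812543e-01   6   6   4   2
 2.9175161938543637e-01   6   6   4   4
 4.0136034315991087e-01   6   6   5   5
 4.4985911173839199e-01   6   6   6   6
-7.0435766894681503e-03   7   1   3   1
 1.1281469487690859e-02   7   1   3   2
-1.9851568260191828e-03   7   1   4   3
 1.3082452300265951e-02   7   1   7   1
 5.9559493854460912e-03   7   2   3   1
 2.1873018348378702e-02   7   2   3   2
 6.6744041747404226e-02   7   2   4   3
-1.0616558221277796e-02   7   2   7   1
 5.7827307838277435e-02   7   2   7   2
-1.6309568662060042e-01   7   3   1   1
-3.0379137373731163e-03   7   3   2   1
-1.9321343552206167e-02   7   3   2   2
 3.5659933511099140e-02   7   3   3   3
 2.7698371109792417e-03   7   3   4   1
 9.4641800712391463e-02   7   3   4   2
 2.9815058207490537e-02   7   3   4   4
-9.1656699112226292e-02   7   3   5   5
-9.1656699112226334e-02   7   3   6   6
 9.8440046619182750e-02   7   3   7   3
-6.8621262998424595e-03   7   4   3   1
 1.1976548206837072e-01   7   4   3   2
 9.7070294705027621e-02   7   4   4   3
 1.2548160829763637e-02   7   4   7   1
 2.0526207901556848e-02   7   4   7   2
 1.1560489835331171e-01   7   4   7   4
-1.1333720366850823e-02   7   5   5   3
 1.8055476640764484e-02   7   5   7   5
-1.1333720366850828e-02   7   6   6   3
 1.8055476640764491e-02   7   6   7   6
 4.8798462745677912e-01   7   7   1   1
 5.7618114720815053e-03   7   7   2   1
 3.3830397660694556e-01   7   7   2   2
 3.3200731436723474e-01   7   7   3   3
-4.9133379725128908e-03   7   7   4   1
-2.3705379874303906e-02   7   7   4   2
 3.3389021800502805e-01   7   7   4   4
 3.5091616217517219e-01   7   7   5   5
 3.5091616217517241e-01   7   7   6   6
-3.6266096918422981e-02   7   7   7   3
 3.7889115968230147e-01   7   7   7   7
-8.2996126772177519e+00   1   1   0   0
-2.0908286455698177e-01   2   1   0   0
-1.9546611306065909e+00   2   2   0   0
-1.7165756406375388e+00   3   3   0   0
 1.8100755002956526e-01   4   1   0   0
 3.5456002641746814e-01   4   2   0   0
-1.6875478852333143e+00   4   4   0   0
-2.0523637870640119e+00   5   5   0   0
-2.0523637870640132e+00   6   6   0   0
 3.4400356848889291e-01   7   3   0   0
-1.8365836963369109e+00   7   7   0   0
 1.8820110011194560e+00   0   0   0   0
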