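 &FCI NORB=7,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,1,
  ISYM=1,
 &END
 2.2725569846279732e+00   1   1   1   1
 1.8348728049396917e-01   2   1   1   1
 2.2980478808885103e-02   2   1   2   1
 4.3875367809475002e-01   2   2   1   1
 5.4623761279937264e-03   2   2   2   1
 3.5353665795987482e-01   2   2   2   2
 4.5612858649074139e-03   3   1   3   1
-9.0492267518279511e-03   3   2   3   1
 1.5158326537586708e-01   3   2   3   2
 3.8707579857378721e-01   3   3   1   1
 2.1149630882463283e-03   3   3   2   1
 3.6244504724803567e-01   3   3   2   2
 3.8633921029495588e-01   3   3   3   3
 1.5716775596807755e-02   4   1   4   1
-1.4863210304775184e-02   4   2   4   1
 4.6785242850691494e-02   4   2   4   2
 1.0681765944901301e-02   4   3   4   3
 5.6919251489445100e-01   4   4   1   1
 6.8894722122674621e-03   4   4   2   1
 3.4147391688242917e-01   4   4   2   2
 3.1434209146526915e-01   4   4   3   3
 4.4985911173839199e-01   4   4   4   4
 1.5716775596807762e-02   5   1   5   1
-1.4863210304775193e-02   5   2   5   1
 4.6785242850691529e-02   5   2   5   2
 1.0681765944901309e-02   5   3   5   3
 2.4249384289240380e-02   5   4   5   4
 5.6919251489445144e-01   5   5   1   1
 6.8894722122674855e-03   5   5   2   1
 3.4147391688242940e-01   5   5   2   2
 3.1434209146526942e-01   5   5   3   3
 4.0136034315991131e-01   5   5   4   4
 4.4985911173839260e-01   5   5   5   5
 1.9151626300345284e-01   6   1   1   1
 2.4330441364624221e-02   6   1   2   1
 5.5808288165512436e-03   6   1   2   2
 2.3611339110211978e-03   6   1   3   3
 6.0498451630002677e-03   6   1   4   4
 6.0498451630002720e-03   6   1   5   5
 2.5793479926852367e-02   6   1   6   1
 1.5266213406739670e-01   6   2   1   1
 5.6623709844284414e-03   6   2   2   1
-6.8269646406328537e-03   6   2   2   2
-3.9286778242228988e-02   6   2   3   3
 7.9472392816846191e-02   6   2   4   4
 7.9472392816846246e-02   6   2   5   5
 5.4597783696247477e-03   6   2   6   1
 8.8991980226669806e-02   6   2   6   2
-5.7117340230244365e-04   6   3   3   1
-9.2637848065380154e-02   6   3   3   2
 9.4366491118596185e-02   6   3   6   3
-1.5701765825712866e-02   6   4   4   1
 4.5711134709179077e-02   6   4   4   2
 4.6808330970878685e-02   6   4   6   4
-1.5701765825712876e-02   6   5   5   1
 4.5711134709179112e-02   6   5   5   2
 4.6808330970878734e-02   6   5   6   5
 4.3767523479001413e-01   6   6   1   1
 6.2998790272361573e-03   6   6   2   1
 3.5705696079850957e-01   6   6   2   2
 3.6864150379836547e-01   6   6   3   3
 3.3634873500431572e-01   6   6   4   4
 3.3634873500431595e-01   6   6   5   5
 6.2040745246876661e-03   6   6   6   1
-2.4900877381671422e-02   6   6   6   2
 3.7479179929841444e-01   6   6   6   6
-8.4620520039840746e-03   7   1   3   1
 1.5124409922010671e-02   7   1   3   2
 1.3437912158316106e-03   7   1   6   3
 1.5753283183926759e-02   7   1   7   1
 5.0517121727112792e-03   7   2   3   1
 3.5194004963224723e-02   7   2   3   2
-6.4896013818132953e-02   7   2   6   3
-8.9064798021029883e-03   7   2   7   1
 5.8159399096835346e-02   7   2   7   2
-1.5576979594223608e-01   7   3   1   1
-3.4722696021844759e-03   7   3   2   1
-5.1937691282003809e-03   7   3   2   2
 1.9680020183578600e-02   7   3   3   3
-7.8306183356136788e-02   7   3   4   4
-7.8306183356136844e-02   7   3   5   5
-3.4204899931311347e-03   7   3   6   1
-8.4586007727569967e-02   7   3   6   2
 1.9498623655115888e-02   7   3   6   6
 9.1813841920515921e-02   7   3   7   3
-1.2708231888678157e-02   7   4   4   3
 1.7159091414281593e-02   7   4   7   4
-1.2708231888678164e-02   7   5   5   3
 1.7159091414281600e-02   7   5   7   5
 8.7795728069954108e-03   7   6   3   1
-1.3560612715581347e-01   7   6   3   2
 9.0363433464255946e-02   7   6   6   3
-1.5097505334726410e-02   7   6   7   1
-4.0266051561173258e-02   7   6   7   2
 1.3206397162125755e-01   7   6   7   6
 5.1938397304639528e-01   7   7   1   1
 6.5055261000783789e-03   7   7   2   1
 3.7717535930423451e-01   7   7   2   2
 3.8946885551024191e-01   7   7   3   3
 3.6569274918849981e-01   7   7   4   4
 3.6569274918850014e-01   7   7   5   5
 6.4616396594014691e-03   7   7   6   1
-6.0842329617283785e-03   7   7   6   2
 3.8642259503851112e-01   7   7   6   6
-1.2938905453112220e-02   7   7   7   3
 4.2520899142975233e-01   7   7   7   7
-8.4441352992352421e+00   1   1   0   0
-2.0222880955016556e-01   2   1   0   0
-2.1631946508814184e+00   2   2   0   0
-2.0625695549994334e+00   3   3   0   0
-2.1655381453751787e+00   4   4   0   0
-2.1655381453751805e+00   5   5   0   0
-2.0230899087374882e-01   6   1   0   0
-2.8823115371587749e-01   6   2   0   0
-1.8500341055712535e+00   6   6   0   0
 3.2897906290111700e-01   7   3   0   0
-1.8655788420229300e+00   7   7   0   0
 2.4988923848197224e+00   0   0   0   0
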