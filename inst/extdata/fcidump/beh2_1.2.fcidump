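 &FCI NORB=7,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,1,
  ISYM=1,
 &END
 2.2713635344237910e+00   1   1   1   1
-2.1056692143442149e-01   2   1   1   1
 2.9901773644856560e-02   2   1   2   1
 5.1057758151731192e-01   2   2   1   1
-7.7774784597217667e-03   2   2   2   1
 4.1389206374876897e-01   2   2   2   2
 6.9021683310418131e-03   3   1   3   1
 1.6700497319582810e-02   3   2   3   1
 1.6666514115881390e-01   3   2   3   2
 4.8233785159612907e-01   3   3   1   1
-3.1770527845531664e-03   3   3   2   1
 4.2734798206992186e-01   3   3   2   2
 4.5015423240107966e-01   3   3   3   3
 1.5765551711730521e-02   4   1   4   1
 1.5635698640485852e-02   4   2   4   1
 5.1200377892377892e-02   4   2   4   2
 1.6006456927146376e-02   4   3   4   3
 5.6916208781133504e-01   4   4   1   1
-8.7119251845311670e-03   4   4   2   1
 3.7936026554217456e-01   4   4   2   2
 3.6859055523188372e-01   4   4   3   3
 4.4985911173839166e-01   4   4   4   4
 1.5765551711730538e-02   5   1   5   1
 1.5635698640485866e-02   5   2   5   1
 5.1200377892377948e-02   5   2   5   2
 1.6006456927146393e-02   5   3   5   3
 2.4249384289240405e-02   5   4   5   4
 5.6916208781133559e-01   5   5   1   1
-8.7119251845311531e-03   5   5   2   1
 3.7936026554217489e-01   5   5   2   2
 3.6859055523188411e-01   5   5   3   3
 4.0136034315991131e-01   5   5   4   4
 4.4985911173839266e-01   5   5   5   5
-1.6413018664704948e-01   6   1   1   1
 2.4003564336453509e-02   6   1   2   1
-7.3361580942233632e-03   6   1   2   2
-4.9704276915828573e-03   6   1   3   3
-3.7791812293043446e-03   6   1   4   4
-3.7791812293043485e-03   6   1   5   5
 1.9669932948950707e-02   6   1   6   1
 9.0606963290897999e-02   6   2   1   1
-6.9958777615902424e-03   6   2   2   1
-3.1999780856645850e-02   6   2   2   2
-5.4199901128725185e-02   6   2   3   3
 4.1779790792714669e-02   6   2   4   4
 4.1779790792714711e-02   6   2   5   5
-2.4273953272604446e-03   6   2   6   1
 7.4976746861237800e-02   6   2   6   2
-4.7177152847819774e-03   6   3   3   1
-9.7648204364453386e-02   6   3   3   2
 8.3188959643151011e-02   6   3   6   3
 1.6145462129360209e-02   6   4   4   1
 4.7726023199120275e-02   6   4   4   2
 5.1122190372098184e-02   6   4   6   4
 1.6145462129360223e-02   6   5   5   1
 4.7726023199120331e-02   6   5   5   2
 5.1122190372098232e-02   6   5   6   5
 4.8079088275739440e-01   6   6   1   1
-6.0441239432432398e-03   6   6   2   1
 4.0913048560567922e-01   6   6   2   2
 4.2001338641804598e-01   6   6   3   3
 3.7484212769512931e-01   6   6   4   4
 3.7484212769512970e-01   6   6   5   5
-5.2824639307152916e-03   6   6   6   1
-4.1305598015190098e-02   6   6   6   2
 4.2171976395721716e-01   6   6   6   6
 1.2349251881529060e-02   7   1   3   1
 2.1727839820770582e-02   7   1   3   2
-3.8772586958691416e-03   7   1   6   3
 2.2869390898645096e-02   7   1   7   1
 2.4114709091942396e-03   7   2   3   1
-4.8157681423457027e-02   7   2   3   2
 6.1162239029705003e-02   7   2   6   3
 6.2466563496792636e-03   7   2   7   1
 5.6537257164446998e-02   7   2   7   2
 1.2889399942889287e-01   7   3   1   1
-5.9482075446857302e-03   7   3   2   1
-1.1998516574396345e-02   7   3   2   2
-2.6688390289982329e-02   7   3   3   3
 5.0656773901638821e-02   7   3   4   4
 5.0656773901638877e-02   7   3   5   5
-2.6358672949375037e-03   7   3   6   1
 6.9953389861556761e-02   7   3   6   2
-3.2814832994219743e-02   7   3   6   6
 7.9623314632326359e-02   7   3   7   3
 1.3949846589316185e-02   7   4   4   3
 1.6089032566773503e-02   7   4   7   4
 1.3949846589316202e-02   7   5   5   3
 1.6089032566773517e-02   7   5   7   5
 1.2485630910781278e-02   7   6   3   1
 1.4424177115845521e-01   7   6   3   2
-9.8865635152483894e-02   7   6   6   3
 1.5860382034097373e-02   7   6   7   1
-6.1350311619384076e-02   7   6   7   2
 1.4356381237862945e-01   7   6   7   6
 5.9360470279369171e-01   7   7   1   1
-9.9870901215387050e-03   7   7   2   1
 4.4546326917248807e-01   7   7   2   2
 4.6518006976996235e-01   7   7   3   3
 3.9831273990652027e-01   7   7   4   4
 3.9831273990652072e-01   7   7   5   5
-9.3126397547458745e-03   7   7   6   1
-5.0155058950229231e-02   7   7   6   2
 4.5071810774961857e-01   7   7   6   6
-2.4109168235870827e-02   7   7   7   3
 5.0988614880805572e-01   7   7   7   7
-8.7372446984813905e+00   1   1   0   0
 2.4139900279176910e-01   2   1   0   0
-2.5735561382719654e+00   2   2   0   0
-2.5449243336818599e+00   3   3   0   0
-2.3438635684197888e+00   4   4   0   0
-2.3438635684197915e+00   5   5   0   0
 1.7702976551801389e-01   6   1   0   0
-1.1445898318286199e-01   6   2   0   0
-1.9190782585124169e+00   6   6   0   0
-2.4291100506278074e-01   7   3   0   0
-1.7156970156848481e+00   7   7   0   0
 3.7483385772295832e+00   0   0   0   0
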