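 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6598093434008789e+00   1   1   1   1
 1.0043253761324275e-01   2   1   1   1
 1.0130435353446645e-02   2   1   2   1
 2.7749431862783697e-01   2   2   1   1
-6.5285846433687773e-04   2   2   2   1
 4.1164959884765834e-01   2   2   2   2
-1.4298714573092117e-01   3   1   1   1
-1.1624007383185510e-02   3   1   2   1
-8.1108614824065284e-03   3   1   2   2
 2.1638420700836963e-02   3   1   3   1
-5.5040302574834658e-02   3   2   1   1
-2.6104851054672214e-03   3   2   2   1
 8.0895381619634388e-02   3   2   2   2
 8.8623231112129228e-04   3   2   3   1
 4.7182970257019445e-02   3   2   3   2
 3.7567380555932195e-01   3   3   1   1
 7.4324405365123105e-03   3   3   2   1
 2.1926062818022857e-01   3   3   2   2
-4.1269970261667419e-04   3   3   3   1
-1.7983471406175889e-02   3   3   3   2
 3.0543444392108027e-01   3   3   3   3
 9.7865230164257376e-03   4   1   4   1
-7.5695439826993956e-03   4   2   4   1
 2.1265564044865529e-02   4   2   4   2
 1.0493918192357942e-02   4   3   4   1
-2.3116142046711110e-02   4   3   4   2
 4.0946964622615580e-02   4   3   4   3
 3.9635036428077652e-01   4   4   1   1
 3.5101270344229654e-03   4   4   2   1
 2.2112370429181555e-01   4   4   2   2
-5.0547136121143971e-03   4   4   3   1
-2.9653070582257083e-02   4   4   3   2
 2.7120098643779800e-01   4   4   3   3
 3.1294546903540271e-01   4   4   4   4
 9.7865230164257411e-03   5   1   5   1
-7.5695439826993964e-03   5   2   5   1
 2.1265564044865529e-02   5   2   5   2
 1.0493918192357942e-02   5   3   5   1
-2.3116142046711110e-02   5   3   5   2
 4.0946964622615580e-02   5   3   5   3
 1.6869136896862858e-02   5   4   5   4
 3.9635036428077663e-01   5   5   1   1
 3.5101270344229775e-03   5   5   2   1
 2.2112370429181563e-01   5   5   2   2
-5.0547136121144214e-03   5   5   3   1
-2.9653070582257100e-02   5   5   3   2
 2.7120098643779805e-01   5   5   3   3
 2.7920719524167720e-01   5   5   4   4
 3.1294546903540288e-01   5   5   5   5
 5.6487934983806734e-02   6   1   1   1
 7.6960794505111551e-03   6   1   2   1
-6.2113723926576787e-03   6   1   2   2
-3.2483830339868607e-03   6   1   3   1
-3.1703104104973817e-03   6   1   3   2
 1.0623145331920948e-02   6   1   3   3
 1.4826785698924679e-03   6   1   4   4
 1.4826785698924679e-03   6   1   5   5
 9.6105701551093964e-03   6   1   6   1
 9.2068820364809859e-02   6   2   1   1
 4.0888787037900572e-04   6   2   2   1
-9.6169788702643297e-02   6   2   2   2
-5.1719934087342875e-03   6   2   3   1
-6.6193381691520531e-02   6   2   3   2
 5.5026995701277269e-03   6   2   3   3
 4.8523711812524815e-02   6   2   4   4
 4.8523711812524815e-02   6   2   5   5
-2.9070464916047646e-03   6   2   6   1
 1.2810298420210925e-01   6   2   6   2
 3.8132881189229598e-02   6   3   1   1
 2.1888748563507550e-03   6   3   2   1
-7.5605984974386434e-02   6   3   2   2
 3.7610725369098871e-03   6   3   3   1
-3.9702897606907699e-02   6   3   3   2
 3.5232317505284348e-02   6   3   3   3
 1.8354353443607849e-02   6   3   4   4
 1.8354353443607852e-02   6   3   5   5
 5.7076461005604439e-03   6   3   6   1
 5.0820259309375365e-02   6   3   6   2
 5.0029841097487843e-02   6   3   6   3
-4.5987747856924572e-03   6   4   4   1
 1.5705943660457737e-02   6   4   4   2
-8.2664571192272805e-03   6   4   4   3
 1.7166210555526897e-02   6   4   6   4
-4.5987747856924589e-03   6   5   5   1
 1.5705943660457741e-02   6   5   5   2
-8.2664571192272857e-03   6   5   5   3
 1.7166210555526900e-02   6   5   6   5
 3.4139118418881548e-01   6   6   1   1
 4.7924751162621874e-04   6   6   2   1
 3.6842623616245790e-01   6   6   2   2
-8.8491371742733371e-03   6   6   3   1
 5.0769155023882857e-02   6   6   3   2
 2.4677305059375201e-01   6   6   3   3
 2.4974219925042990e-01   6   6   4   4
 2.4974219925042995e-01   6   6   5   5
-5.2432867973939545e-03   6   6   6   1
-5.2056119713269386e-02   6   6   6   2
-4.5579662175967463e-02   6   6   6   3
 3.5706541764591171e-01   6   6   6   6
-4.5865174301340410e+00   1   1   0   0
-9.9779679148837619e-02   2   1   0   0
-1.1445537057915687e+00   2   2   0   0
 1.5659838359028186e-01   3   1   0   0
 1.7561216146276471e-02   3   2   0   0
-1.0605212956343533e+00   3   3   0   0
-1.0509131275412285e+00   4   4   0   0
-1.0509131275412287e+00   5   5   0   0
-4.3656302328015144e-02   6   1   0   0
-8.0271772576082853e-02   6   2   0   0
 5.5044428449833342e-03   6   3   0   0
-1.0195430158341192e+00   6   6   0   0
 5.6697558311035712e-01   0   0   0   0
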