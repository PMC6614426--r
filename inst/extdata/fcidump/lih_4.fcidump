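 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6603418078754970e+00   1   1   1   1
 1.1558137628945411e-01   2   1   1   1
 1.2575886537675204e-02   2   1   2   1
 2.4969221795006485e-01   2   2   1   1
 1.9129443089403260e-03   2   2   2   1
 3.6161864818965567e-01   2   2   2   2
 1.3948187942993182e-01   3   1   1   1
 1.4433642582183727e-02   3   1   2   1
 4.5424346836031278e-03   3   1   2   2
 1.8611818505675788e-02   3   1   3   1
 1.1852932441339212e-01   3   2   1   1
 3.1785640092429949e-03   3   2   2   1
-1.2793370351691277e-01   3   2   2   2
 2.9055057466535741e-03   3   2   3   1
 1.5433304524085642e-01   3   2   3   2
 3.0653239694164353e-01   3   3   1   1
 4.6727045281645067e-03   3   3   2   1
 2.8901462361916147e-01   3   3   2   2
 3.6022576773719539e-03   3   3   3   1
-5.0819338698412042e-02   3   3   3   2
 2.7840371913936207e-01   3   3   3   3
 9.7668969069382126e-03   4   1   4   1
-8.6556361133080465e-03   4   2   4   1
 2.5365449173093128e-02   4   2   4   2
-1.0376716609240173e-02   4   3   4   1
 2.8919055325229193e-02   4   3   4   2
 3.6642682925657713e-02   4   3   4   3
 3.9635901460823364e-01   4   4   1   1
 3.9861082882274752e-03   4   4   2   1
 1.9688710370081378e-01   4   4   2   2
 4.8203491165242371e-03   4   4   3   1
 7.0473850541809158e-02   4   4   3   2
 2.2979199525991004e-01   4   4   3   3
 3.1294546903540288e-01   4   4   4   4
 9.7668969069382109e-03   5   1   5   1
-8.6556361133080430e-03   5   2   5   1
 2.5365449173093118e-02   5   2   5   2
-1.0376716609240173e-02   5   3   5   1
 2.8919055325229190e-02   5   3   5   2
 3.6642682925657706e-02   5   3   5   3
 1.6869136896862858e-02   5   4   5   4
 3.9635901460823353e-01   5   5   1   1
 3.9861082882274483e-03   5   5   2   1
 1.9688710370081369e-01   5   5   2   2
 4.8203491165241972e-03   5   5   3   1
 7.0473850541809144e-02   5   5   3   2
 2.2979199525990998e-01   5   5   3   3
 2.7920719524167714e-01   5   5   4   4
 3.1294546903540282e-01   5   5   5   5
-1.5459593651142118e-02   6   1   1   1
-3.2269766972187197e-03   6   1   2   1
 4.4239547428138078e-03   6   1   2   2
 4.1063769047843787e-04   6   1   3   1
-2.3603815015549841e-03   6   1   3   2
-4.4908660268789457e-03   6   1   3   3
-3.2386622008639824e-04   6   1   4   4
-3.2386622008639813e-04   6   1   5   5
 9.1036853547557719e-03   6   1   6   1
-5.9946360608036139e-02   6   2   1   1
 2.5523801101532030e-04   6   2   2   1
 4.8356021832702351e-02   6   2   2   2
-3.3374746266682772e-03   6   2   3   1
-7.1911637358837141e-02   6   2   3   2
 3.6957334458048142e-02   6   2   3   3
-3.5333784578252495e-02   6   2   4   4
-3.5333784578252488e-02   6   2   5   5
-7.2642964636544689e-03   6   2   6   1
 6.0531248948104854e-02   6   2   6   2
 4.6792678566871623e-02   6   3   1   1
 2.1246704778833839e-03   6   3   2   1
-7.5791888877247360e-02   6   3   2   2
-2.0716973719493814e-03   6   3   3   1
 7.6936374082249098e-02   6   3   3   2
-1.2897254263176717e-02   6   3   3   3
 2.6782283667272568e-02   6   3   4   4
 2.6782283667272561e-02   6   3   5   5
-9.6066160291422825e-03   6   3   6   1
-1.1385532671824104e-02   6   3   6   2
 6.6616571901961255e-02   6   3   6   3
 1.3757623101868875e-03   6   4   4   1
-6.7164869506771297e-03   6   4   4   2
-4.9422142804868318e-04   6   4   4   3
 1.5895573826213660e-02   6   4   6   4
 1.3757623101868870e-03   6   5   5   1
-6.7164869506771288e-03   6   5   5   2
-4.9422142804868329e-04   6   5   5   3
 1.5895573826213656e-02   6   5   6   5
 3.7348733338862639e-01   6   6   1   1
 3.2265178889853193e-03   6   6   2   1
 2.4285245259974919e-01   6   6   2   2
 5.2226269338914010e-03   6   6   3   1
 2.3885878097097971e-02   6   6   3   2
 2.4808813939292484e-01   6   6   3   3
 2.6573437087737878e-01   6   6   4   4
 2.6573437087737872e-01   6   6   5   5
 2.3906487844982333e-03   6   6   6   1
-2.5479131256720539e-02   6   6   6   2
 6.3810147852982587e-03   6   6   6   3
 2.9311275869034148e-01   6   6   6   6
-4.5301480563497369e+00   1   1   0   0
-1.1749432059907625e-01   2   1   0   0
-9.7856998374459758e-01   2   2   0   0
-1.4538818478888749e-01   3   1   0   0
-9.4691302841764149e-02   3   2   0   0
-9.8369541182609865e-01   3   3   0   0
-1.0044353239174466e+00   4   4   0   0
-1.0044353239174464e+00   5   5   0   0
 6.8669221724674450e-03   6   1   0   0
 6.8309722735369130e-02   6   2   0   0
-1.3502579121219519e-02   6   3   0   0
-1.0005682817247767e+00   6   6   0   0
 3.9688290817724997e-01   0   0   0   0
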