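 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6585666730090911e+00   1   1   1   1
 1.1170996034469348e-01   2   1   1   1
 1.3337575759943975e-02   2   1   2   1
 3.6670103326967263e-01   2   2   1   1
-6.2103026528733318e-03   2   2   2   1
 4.8731097390152411e-01   2   2   2   2
-1.3857462965059036e-01   3   1   1   1
-1.1215771776684879e-02   3   1   2   1
-1.5868083116753046e-02   3   1   2   2
 2.1662245608805118e-02   3   1   3   1
-1.3451286929533393e-02   3   2   1   1
-3.3493883663064865e-03   3   2   2   1
 4.8579544355855528e-02   3   2   2   2
-1.7627508375267850e-04   3   2   3   1
 1.3063965407137709e-02   3   2   3   2
 3.9563371413766762e-01   3   3   1   1
 1.1035060783698728e-02   3   3   2   1
 2.2361002306471972e-01   3   3   2   2
 1.8246210710218479e-03   3   3   3   1
-7.4841723133538679e-03   3   3   3   2
 3.3788228364008960e-01   3   3   3   3
 9.8178834576699500e-03   4   1   4   1
-7.4884628160526131e-03   4   2   4   1
 2.3422669343930693e-02   4   2   4   2
 1.0257702234251600e-02   4   3   4   1
-1.9276889970960543e-02   4   3   4   2
 4.1276696448270825e-02   4   3   4   3
 3.9631934080186559e-01   4   4   1   1
 4.3558019365809017e-03   4   4   2   1
 2.7017147476003983e-01   4   4   2   2
-4.9752917864409486e-03   4   4   3   1
-5.7675091509280883e-03   4   4   3   2
 2.8199132767449303e-01   4   4   3   3
 3.1294546903540255e-01   4   4   4   4
 9.8178834576699587e-03   5   1   5   1
-7.4884628160526183e-03   5   2   5   1
 2.3422669343930707e-02   5   2   5   2
 1.0257702234251610e-02   5   3   5   1
-1.9276889970960560e-02   5   3   5   2
 4.1276696448270860e-02   5   3   5   3
 1.6869136896862848e-02   5   4   5   4
 3.9631934080186593e-01   5   5   1   1
 4.3558019365809155e-03   5   5   2   1
 2.7017147476004005e-01   5   5   2   2
-4.9752917864409702e-03   5   5   3   1
-5.7675091509281108e-03   5   5   3   2
 2.8199132767449325e-01   5   5   3   3
 2.7920719524167709e-01   5   5   4   4
 3.1294546903540299e-01   5   5   5   5
 5.3045028684218468e-02   6   1   1   1
 8.9066749433753690e-03   6   1   2   1
-6.8375739192153224e-03   6   1   2   2
-2.3559102481144991e-03   6   1   3   1
-1.6892837390450638e-03   6   1   3   2
 1.0443529031824720e-02   6   1   3   3
 5.9107899788737579e-04   6   1   4   4
 5.9107899788737623e-04   6   1   5   5
 8.5495086365868118e-03   6   1   6   1
 4.1496880833872950e-02   6   2   1   1
 4.6926674017233484e-03   6   2   2   1
-1.2679500131775648e-01   6   2   2   2
-5.5964783913086389e-04   6   2   3   1
-3.4600608527807823e-02   6   2   3   2
 1.2416028790697661e-02   6   2   3   3
 1.6292229150999721e-02   6   2   4   4
 1.6292229150999735e-02   6   2   5   5
-1.1914642775806810e-04   6   2   6   1
 1.2392646460273204e-01   6   2   6   2
 1.7665804348522746e-02   6   3   1   1
 3.6667886526872643e-03   6   3   2   1
-5.1366877956979876e-02   6   3   2   2
 4.3956300852274876e-03   6   3   3   1
-9.4085916338881113e-03   6   3   3   2
 3.5979630842067387e-02   6   3   3   3
 2.2380880191185202e-03   6   3   4   4
 2.2380880191185215e-03   6   3   5   5
 4.3058564661326770e-03   6   3   6   1
 3.1903615366901068e-02   6   3   6   2
 2.6448168239536097e-02   6   3   6   3
-6.1123266830491732e-03   6   4   4   1
 1.9574473445812091e-02   6   4   4   2
-1.3722971879628962e-02   6   4   4   3
 1.9722257579779575e-02   6   4   6   4
-6.1123266830491775e-03   6   5   5   1
 1.9574473445812104e-02   6   5   5   2
-1.3722971879628978e-02   6   5   5   3
 1.9722257579779582e-02   6   5   6   5
 3.6173103602316697e-01   6   6   1   1
-3.2715967226568617e-03   6   6   2   1
 4.5384444050411399e-01   6   6   2   2
-1.1336336858491936e-02   6   6   3   1
 4.3353417876425229e-02   6   6   3   2
 2.4143562478871142e-01   6   6   3   3
 2.6812839821127205e-01   6   6   4   4
 2.6812839821127227e-01   6   6   5   5
-3.0683869246969668e-03   6   6   6   1
-1.3420543470444782e-01   6   6   6   2
-4.4076918361432703e-02   6   6   6   3
 4.5378723088225348e-01   6   6   6   6
-4.7273931203518904e+00   1   1   0   0
-1.0549965763042231e-01   2   1   0   0
-1.4926462174996906e+00   2   2   0   0
 1.6696140764565287e-01   3   1   0   0
-3.2892742534629454e-02   3   2   0   0
-1.1255447134746610e+00   3   3   0   0
-1.1357997754998019e+00   4   4   0   0
-1.1357997754998030e+00   5   5   0   0
-3.4677213317248337e-02   6   1   0   0
 5.2707915011624216e-02   6   2   0   0
 3.0445628738520344e-02   6   3   0   0
-9.5096657684116181e-01   6   6   0   0
 9.9220727044312496e-01   0   0   0   0
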