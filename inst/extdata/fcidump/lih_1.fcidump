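 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6454044195993522e+00   1   1   1   1
 1.6278428733334777e-01   2   1   1   1
 3.1693290590846461e-02   2   1   2   1
 4.6837493847033279e-01   2   2   1   1
-1.4857929736184194e-02   2   2   2   1
 5.2426312446724510e-01   2   2   2   2
-1.2588937986538010e-01   3   1   1   1
-1.3658124409346615e-02   3   1   2   1
-2.5706305777713195e-02   3   1   2   2
 1.9459104728168294e-02   3   1   3   1
-1.9499138390634935e-03   3   2   1   1
-6.5416248036698904e-03   3   2   2   1
 3.8811837276942020e-02   3   2   2   2
-6.2032149487688899e-04   3   2   3   1
 9.4659262465927978e-03   3   2   3   2
 3.9409243266661281e-01   3   3   1   1
 1.6302312314586374e-02   3   3   2   1
 2.4664689109957966e-01   3   3   2   2
 3.2578751399659086e-03   3   3   3   1
 1.3893846766767923e-03   3   3   3   2
 3.3900401566352184e-01   3   3   3   3
 9.8908252363100017e-03   4   1   4   1
-8.3115481234478910e-03   4   2   4   1
 2.7182111458672623e-02   4   2   4   2
 1.0249557370841916e-02   4   3   4   1
-1.9558157624965267e-02   4   3   4   2
 4.2362364644267188e-02   4   3   4   3
 3.9608898586935576e-01   4   4   1   1
 6.0042066762130628e-03   4   4   2   1
 3.0049905313266184e-01   4   4   2   2
-4.3819412232363776e-03   4   4   3   1
-8.1511682624134905e-04   4   4   3   2
 2.8275047603143710e-01   4   4   3   3
 3.1294546903540321e-01   4   4   4   4
 9.8908252363100017e-03   5   1   5   1
-8.3115481234478893e-03   5   2   5   1
 2.7182111458672619e-02   5   2   5   2
 1.0249557370841917e-02   5   3   5   1
-1.9558157624965267e-02   5   3   5   2
 4.2362364644267188e-02   5   3   5   3
 1.6869136896862872e-02   5   4   5   4
 3.9608898586935576e-01   5   5   1   1
 6.0042066762130628e-03   5   5   2   1
 3.0049905313266184e-01   5   5   2   2
-4.3819412232363776e-03   5   5   3   1
-8.1511682624134905e-04   5   5   3   2
 2.8275047603143710e-01   5   5   3   3
 2.7920719524167753e-01   5   5   4   4
 3.1294546903540321e-01   5   5   5   5
-6.9054225594727250e-02   6   1   1   1
-1.0987445307452942e-02   6   1   2   1
 5.4238911531003355e-03   6   1   2   2
 9.1852614694619885e-03   6   1   3   1
 4.1128607651985177e-03   6   1   3   2
-3.2196626524564243e-04   6   1   3   3
-3.2746087001247568e-03   6   1   4   4
-3.2746087001247568e-03   6   1   5   5
 7.0977384114465610e-03   6   1   6   1
-8.8768317835825547e-02   6   2   1   1
 1.2547769647106893e-02   6   2   2   1
-1.5993535308555526e-01   6   2   2   2
 1.2961561994769258e-02   6   2   3   1
-2.8948393264031945e-02   6   2   3   2
-1.5385927676760948e-02   6   2   3   3
-2.2943362466662502e-02   6   2   4   4
-2.2943362466662499e-02   6   2   5   5
-8.4114649091413998e-03   6   2   6   1
 1.2241564121473016e-01   6   2   6   2
 2.1068145961014924e-02   6   3   1   1
 1.0971048775878735e-02   6   3   2   1
-4.8578317983467185e-02   6   3   2   2
 5.1677795224901553e-03   6   3   3   1
-4.8367870463253458e-03   6   3   3   2
 3.6333072392398358e-02   6   3   3   3
-4.0674948123010300e-04   6   3   4   4
-4.0674948123010300e-04   6   3   5   5
-1.5867975933846516e-03   6   3   6   1
 2.8987917157286998e-02   6   3   6   2
 2.6932118659562843e-02   6   3   6   3
-3.6338770280618256e-03   6   4   4   1
 1.6126609602385017e-02   6   4   4   2
-1.2199538486607354e-02   6   4   4   3
 1.5331950369701275e-02   6   4   6   4
-3.6338770280618256e-03   6   5   5   1
 1.6126609602385013e-02   6   5   5   2
-1.2199538486607351e-02   6   5   5   3
 1.5331950369701275e-02   6   5   6   5
 3.8377584523558023e-01   6   6   1   1
-1.4864164587350948e-02   6   6   2   1
 4.5939095196965618e-01   6   6   2   2
-1.6123101327022365e-02   6   6   3   1
 3.6131965328166982e-02   6   6   3   2
 2.4426134876753164e-01   6   6   3   3
 2.7247272647325443e-01   6   6   4   4
 2.7247272647325443e-01   6   6   5   5
 1.0076605320722283e-02   6   6   6   1
-1.5572012628971696e-01   6   6   6   2
-3.9863410830766118e-02   6   6   6   3
 4.3975879156958508e-01   6   6   6   6
-4.9213604111878801e+00   1   1   0   0
-1.4792635762686793e-01   2   1   0   0
-1.7459768333876453e+00   2   2   0   0
 1.7076036660459293e-01   3   1   0   0
-4.8570133979220380e-02   3   2   0   0
-1.1757052005232078e+00   3   3   0   0
-1.1981644575678823e+00   4   4   0   0
-1.1981644575678823e+00   5   5   0   0
 7.0754212942573155e-02   6   1   0   0
 3.2648454340965916e-01   6   2   0   0
 3.5257212221991928e-02   6   3   0   0
-9.4382098207572818e-01   6   6   0   0
 1.5875316327089999e+00   0   0   0   0
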