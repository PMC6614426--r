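 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6589498465550929e+00   1   1   1   1
-1.0439514813260992e-01   2   1   1   1
 1.1540927323545844e-02   2   1   2   1
 3.4451575538188289e-01   2   2   1   1
 4.5907968157586935e-03   2   2   2   1
 4.7361333241868542e-01   2   2   2   2
 1.4002200595166370e-01   3   1   1   1
-1.0781126171399747e-02   3   1   2   1
 1.3825429864113436e-02   3   1   2   2
 2.1868590088234781e-02   3   1   3   1
-1.8055699479548475e-02   3   2   1   1
 2.9176562884018747e-03   3   2   2   1
 5.2197682656066474e-02   3   2   2   2
 4.9582131942051225e-05   3   2   3   1
 1.5426704708144848e-02   3   2   3   2
 3.9451633881957393e-01   3   3   1   1
-1.0019418727572341e-02   3   3   2   1
 2.1855100221000648e-01   3   3   2   2
-1.4877455092080760e-03   3   3   3   1
-1.0126754220328519e-02   3   3   3   2
 3.3526615646259267e-01   3   3   3   3
 9.8151706688706236e-03   4   1   4   1
 7.3558110395383685e-03   4   2   4   1
 2.2412000311751803e-02   4   2   4   2
-1.0297707500527229e-02   4   3   4   1
-1.9529031173947387e-02   4   3   4   2
 4.1283072825820118e-02   4   3   4   3
 3.9633173604702243e-01   4   4   1   1
-3.9790747591011595e-03   4   4   2   1
 2.6049030263482459e-01   4   4   2   2
 5.0232549424945499e-03   4   4   3   1
-8.2051667787296362e-03   4   4   3   2
 2.8137760539561535e-01   4   4   3   3
 3.1294546903540377e-01   4   4   4   4
 9.8151706688706271e-03   5   1   5   1
 7.3558110395383703e-03   5   2   5   1
 2.2412000311751810e-02   5   2   5   2
-1.0297707500527232e-02   5   3   5   1
-1.9529031173947393e-02   5   3   5   2
 4.1283072825820125e-02   5   3   5   3
 1.6869136896862900e-02   5   4   5   4
 3.9633173604702249e-01   5   5   1   1
-3.9790747591011430e-03   5   5   2   1
 2.6049030263482464e-01   5   5   2   2
 5.0232549424945256e-03   5   5   3   1
-8.2051667787296327e-03   5   5   3   2
 2.8137760539561540e-01   5   5   3   3
 2.7920719524167803e-01   5   5   4   4
 3.1294546903540388e-01   5   5   5   5
 6.4236376540204379e-02   6   1   1   1
-9.4620425946001820e-03   6   1   2   1
-7.5674286666234146e-03   6   1   2   2
 3.7271511812871942e-03   6   1   3   1
-2.2671270562465672e-03   6   1   3   2
 1.1401355563437094e-02   6   1   3   3
 1.1499854960099801e-03   6   1   4   4
 1.1499854960099803e-03   6   1   5   5
 1.0188045665816488e-02   6   1   6   1
-6.0509663260825838e-02   6   2   1   1
 3.1000651762447613e-03   6   2   2   1
 1.1786231835012669e-01   6   2   2   2
-2.4074258456423577e-03   6   2   3   1
 3.7420798528200634e-02   6   2   3   2
-1.6468811870785943e-02   6   2   3   3
-2.5425411654591008e-02   6   2   4   4
-2.5425411654591015e-02   6   2   5   5
 1.5265321869396744e-04   6   2   6   1
 1.2640005193649825e-01   6   2   6   2
-1.8993779092813221e-02   6   3   1   1
 2.8694923320578573e-03   6   3   2   1
 5.2892135159178087e-02   6   3   2   2
 4.2055703882218076e-03   6   3   3   1
 1.1755493303606259e-02   6   3   3   2
-3.6024343274932681e-02   6   3   3   3
-4.1353889779889045e-03   6   3   4   4
-4.1353889779889063e-03   6   3   5   5
-4.3551644858438217e-03   6   3   6   1
 3.4127837789832631e-02   6   3   6   2
 2.7343171381156856e-02   6   3   6   3
-6.1515415933975515e-03   6   4   4   1
-1.9359307668448896e-02   6   4   4   2
 1.3223095922082614e-02   6   4   4   3
 1.9818123896773246e-02   6   4   6   4
-6.1515415933975541e-03   6   5   5   1
-1.9359307668448900e-02   6   5   5   2
 1.3223095922082619e-02   6   5   5   3
 1.9818123896773249e-02   6   5   6   5
 3.5984134360530978e-01   6   6   1   1
 1.9310296006549881e-03   6   6   2   1
 4.4434434225001768e-01   6   6   2   2
 1.1246732921870192e-02   6   6   3   1
 4.5682795745901845e-02   6   6   3   2
 2.4006469709647413e-01   6   6   3   3
 2.6496361036366856e-01   6   6   4   4
 2.6496361036366861e-01   6   6   5   5
-4.2506842667817792e-03   6   6   6   1
 1.2089790329976904e-01   6   6   6   2
 4.5009459737954692e-02   6   6   6   3
 4.4400262768550064e-01   6   6   6   6
-4.6908987643986304e+00   1   1   0   0
 9.9804351183719955e-02   2   1   0   0
-1.4188637697927471e+00   2   2   0   0
-1.6475520957362771e-01   3   1   0   0
-2.6867410477009666e-02   3   2   0   0
-1.1127983201691876e+00   3   3   0   0
-1.1179178942447634e+00   4   4   0   0
-1.1179178942447636e+00   5   5   0   0
-4.6001453837696202e-02   6   1   0   0
-6.3050352221116022e-03   6   2   0   0
-2.6648762853651951e-02   6   3   0   0
-9.8209815599393147e-01   6   6   0   0
 8.8196201817166664e-01   0   0   0   0
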