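 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6541449512593107e+00   1   1   1   1
 1.4013453628793274e-01   2   1   1   1
 2.2090450197381244e-02   2   1   2   1
 4.2696195874870069e-01   2   2   1   1
-1.1543403125681553e-02   2   2   2   1
 5.1487681125222884e-01   2   2   2   2
 1.3290095021662074e-01   3   1   1   1
 1.2906719545742174e-02   3   1   2   1
 2.1786709389577042e-02   3   1   2   2
 2.0695750898347284e-02   3   1   3   1
 6.0280642259781395e-03   3   2   1   1
 5.1177358804292894e-03   3   2   2   1
-4.2336956737959626e-02   3   2   2   2
-4.1064118230523265e-04   3   2   3   1
 1.0185073063336171e-02   3   2   3   2
 3.9579591462231239e-01   3   3   1   1
 1.4217681041942931e-02   3   3   2   1
 2.3767209321664526e-01   3   3   2   2
-2.6257412024385520e-03   3   3   3   1
 1.9915864281413228e-03   3   3   3   2
 3.3994708419026742e-01   3   3   3   3
 9.8379486934087514e-03   4   1   4   1
-7.9424981960734865e-03   4   2   4   1
 2.5814498929563851e-02   4   2   4   2
-1.0234762709830947e-02   4   3   4   1
 1.9258482841032331e-02   4   3   4   2
 4.1734229103043183e-02   4   3   4   3
 3.9622505539751202e-01   4   4   1   1
 5.4512910273784307e-03   4   4   2   1
 2.9042491767677886e-01   4   4   2   2
 4.7324596827250714e-03   4   4   3   1
 2.1843755035350714e-03   4   4   3   2
 2.8265711378998681e-01   4   4   3   3
 3.1294546903540310e-01   4   4   4   4
 9.8379486934087549e-03   5   1   5   1
-7.9424981960734900e-03   5   2   5   1
 2.5814498929563858e-02   5   2   5   2
-1.0234762709830951e-02   5   3   5   1
 1.9258482841032338e-02   5   3   5   2
 4.1734229103043204e-02   5   3   5   3
 1.6869136896862869e-02   5   4   5   4
 3.9622505539751218e-01   5   5   1   1
 5.4512910273784472e-03   5   5   2   1
 2.9042491767677897e-01   5   5   2   2
 4.7324596827250922e-03   5   5   3   1
 2.1843755035350939e-03   5   5   3   2
 2.8265711378998692e-01   5   5   3   3
 2.7920719524167747e-01   5   5   4   4
 3.1294546903540338e-01   5   5   5   5
 9.4982140753017454e-03   6   1   1   1
-1.2570899557812127e-03   6   1   2   1
 5.1447358376616160e-04   6   1   2   2
 4.0981029424721205e-03   6   1   3   1
 1.2184246931268852e-03   6   1   3   2
-4.8703134837657603e-03   6   1   3   3
 1.6225201290072124e-03   6   1   4   4
 1.6225201290072130e-03   6   1   5   5
 3.2242059219467359e-03   6   1   6   1
 2.9423451909881052e-02   6   2   1   1
-1.0001485052793866e-02   6   2   2   1
 1.5057901531980447e-01   6   2   2   2
 6.7865502604945241e-03   6   2   3   1
-3.0838123641908854e-02   6   2   3   2
 3.5048521533339923e-03   6   2   3   3
 8.4128556438926878e-03   6   2   4   4
 8.4128556438926912e-03   6   2   5   5
-3.8935032355498353e-03   6   2   6   1
 1.2182565226149226e-01   6   2   6   2
 1.8582982660339125e-02   6   3   1   1
 7.3561841908511205e-03   6   3   2   1
-5.0106351290917291e-02   6   3   2   2
-4.8539014430729385e-03   6   3   3   1
 6.1251824668360618e-03   6   3   3   2
 3.6329598577047886e-02   6   3   3   3
-3.4189603139478164e-04   6   3   4   4
-3.4189603139478175e-04   6   3   5   5
-2.3412846303928238e-03   6   3   6   1
-2.9553329534800866e-02   6   3   6   2
 2.6583794949195518e-02   6   3   6   3
 5.0094014912788198e-03   6   4   4   1
-1.8256489829000824e-02   6   4   4   2
-1.3524781206800045e-02   6   4   4   3
 1.7597624566741670e-02   6   4   6   4
 5.0094014912788216e-03   6   5   5   1
-1.8256489829000837e-02   6   5   5   2
-1.3524781206800052e-02   6   5   5   3
 1.7597624566741670e-02   6   5   6   5
 3.6352767405216491e-01   6   6   1   1
-9.8438285246133187e-03   6   6   2   1
 4.6155837082677476e-01   6   6   2   2
 1.2509380906884320e-02   6   6   3   1
-3.8551020122891237e-02   6   6   3   2
 2.4294113023499270e-01   6   6   3   3
 2.7103678501372686e-01   6   6   4   4
 2.7103678501372697e-01   6   6   5   5
-3.4321382050440524e-03   6   6   6   1
 1.5378636621604136e-01   6   6   6   2
-4.1511071609839426e-02   6   6   6   3
 4.5124947450322239e-01   6   6   6   6
-4.8359189922260146e+00   1   1   0   0
-1.2859113356581589e-01   2   1   0   0
-1.6597047852648759e+00   2   2   0   0
-1.7135663302362569e-01   3   1   0   0
 4.3187547289889751e-02   3   2   0   0
-1.1566281408874828e+00   3   3   0   0
-1.1761917121441079e+00   4   4   0   0
-1.1761917121441086e+00   5   5   0   0
-2.0528646312908055e-02   6   1   0   0
-2.1068300837202619e-01   6   2   0   0
 3.6306716235984061e-02   6   3   0   0
-9.0325066466073611e-01   6   6   0   0
 1.3229430272575000e+00   0   0   0   0
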