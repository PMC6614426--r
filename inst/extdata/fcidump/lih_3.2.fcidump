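 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6600566146939877e+00   1   1   1   1
 1.0580702793302750e-01   2   1   1   1
 1.0936865830847175e-02   2   1   2   1
 2.6454229935735551e-01   2   2   1   1
 3.8263093606143872e-04   2   2   2   1
 3.9111383823520884e-01   2   2   2   2
 1.4256690003837394e-01   3   1   1   1
 1.2715093539958731e-02   3   1   2   1
 6.6984177723306126e-03   3   1   2   2
 2.0845224153578375e-02   3   1   3   1
 7.7123596350620632e-02   3   2   1   1
 2.8430597653312187e-03   3   2   2   1
-9.8660170014817777e-02   3   2   2   2
 1.5048245969027981e-03   3   2   3   1
 7.8106099979816740e-02   3   2   3   2
 3.5657318114859338e-01   3   3   1   1
 6.5209884909898557e-03   3   3   2   1
 2.3852624393863386e-01   3   3   2   2
 1.5602592247451299e-03   3   3   3   1
 7.3943477000460315e-03   3   3   3   2
 2.8691414133911819e-01   3   3   3   3
 9.7772477044553129e-03   4   1   4   1
-7.9644926098044917e-03   4   2   4   1
 2.2546505380951026e-02   4   2   4   2
-1.0508550020429630e-02   4   3   4   1
 2.5410175811824077e-02   4   3   4   2
 3.9906437928319383e-02   4   3   4   3
 3.9635423978478918e-01   4   4   1   1
 3.6623971401788130e-03   4   4   2   1
 2.1080627485512882e-01   4   4   2   2
 4.9990853248732649e-03   4   4   3   1
 4.3279164269706884e-02   4   4   3   2
 2.6026425319226260e-01   4   4   3   3
 3.1294546903540271e-01   4   4   4   4
 9.7772477044553267e-03   5   1   5   1
-7.9644926098045073e-03   5   2   5   1
 2.2546505380951067e-02   5   2   5   2
-1.0508550020429648e-02   5   3   5   1
 2.5410175811824122e-02   5   3   5   2
 3.9906437928319445e-02   5   3   5   3
 1.6869136896862872e-02   5   4   5   4
 3.9635423978478990e-01   5   5   1   1
 3.6623971401788329e-03   5   5   2   1
 2.1080627485512918e-01   5   5   2   2
 4.9990853248732831e-03   5   5   3   1
 4.3279164269706953e-02   5   5   3   2
 2.6026425319226304e-01   5   5   3   3
 2.7920719524167753e-01   5   5   4   4
 3.1294546903540366e-01   5   5   5   5
-4.3127183054892208e-02   6   1   1   1
-6.4178870955630685e-03   6   1   2   1
 5.6224117989928917e-03   6   1   2   2
-1.8230804909632387e-03   6   1   3   1
-3.2592458574763716e-03   6   1   3   2
-9.0980099129085099e-03   6   1   3   3
-1.1341581164661491e-03   6   1   4   4
-1.1341581164661509e-03   6   1   5   5
 9.0139993824334668e-03   6   1   6   1
-8.8275079297387676e-02   6   2   1   1
-1.2438350438967547e-04   6   2   2   1
 8.4498045586250611e-02   6   2   2   2
-5.0438806952295794e-03   6   2   3   1
-7.9216021789628804e-02   6   2   3   2
 1.3728739946619644e-02   6   2   3   3
-4.8869155134816836e-02   6   2   4   4
-4.8869155134816919e-02   6   2   5   5
-4.3932154615344103e-03   6   2   6   1
 1.1176772599085937e-01   6   2   6   2
 4.7782317170478025e-02   6   3   1   1
 2.3617423694499494e-03   6   3   2   1
-8.5963256229206822e-02   6   3   2   2
-3.5112410248902904e-03   6   3   3   1
 6.0838063143575101e-02   6   3   3   2
 2.4285550995593153e-02   6   3   3   3
 2.5055677767712677e-02   6   3   4   4
 2.5055677767712722e-02   6   3   5   5
-7.1313598299695118e-03   6   3   6   1
-4.9746575470786772e-02   6   3   6   2
 6.6040405207751729e-02   6   3   6   3
 3.5387022173926793e-03   6   4   4   1
-1.3182383755481007e-02   6   4   4   2
-5.3332627350727684e-03   6   4   4   3
 1.6122174663721255e-02   6   4   6   4
 3.5387022173926845e-03   6   5   5   1
-1.3182383755481027e-02   6   5   5   2
-5.3332627350727753e-03   6   5   5   3
 1.6122174663721275e-02   6   5   6   5
 3.4588477919530208e-01   6   6   1   1
 1.4072237267019111e-03   6   6   2   1
 3.2618548195900682e-01   6   6   2   2
 7.4434160893974291e-03   6   6   3   1
-3.9258317914841814e-02   6   6   3   2
 2.5718678143538659e-01   6   6   3   3
 2.5106935321881185e-01   6   6   4   4
 2.5106935321881224e-01   6   6   5   5
 4.7250913164576516e-03   6   6   6   1
 1.8388733753843686e-02   6   6   6   2
-3.4283518868941154e-02   6   6   6   3
 3.2002086766790655e-01   6   6   6   6
-4.5630425943383939e+00   1   1   0   0
-1.0618965888020755e-01   2   1   0   0
-1.0734503625485685e+00   2   2   0   0
-1.5312067581960256e-01   3   1   0   0
-4.2871929258854961e-02   3   2   0   0
-1.0376173877503674e+00   3   3   0   0
-1.0323732760417892e+00   4   4   0   0
-1.0323732760417907e+00   5   5   0   0
 3.1757975966992681e-02   6   1   0   0
 8.5634225966677080e-02   6   2   0   0
-4.6772241956920049e-03   6   3   0   0
-1.0118937257159093e+00   6   6   0   0
 4.9610363522156248e-01   0   0   0   0
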