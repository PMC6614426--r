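 &FCI NORB=6,NELEC=6,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 2.9117483522671517e-01   1   1   1   1
 1.1361545921321294e-01   2   1   2   1
 2.2478848286021699e-01   2   2   1   1
 2.7870611138560880e-01   2   2   2   2
-6.2953040159076684e-02   3   1   1   1
 5.3285278531091898e-02   3   1   2   2
 1.1303611634605727e-01   3   1   3   1
 9.6238418975604242e-02   3   2   2   1
 1.1377081958682168e-01   3   2   3   2
 2.6123566218198890e-01   3   3   1   1
 2.3187961266179224e-01   3   3   2   2
-3.0936230720898690e-02   3   3   3   1
 2.6276141179206197e-01   3   3   3   3
 3.9310125729097714e-02   4   1   2   1
-1.8055997603015392e-02   4   1   3   2
 9.5886765261092674e-02   4   1   4   1
 5.1052095885465158e-02   4   2   1   1
-4.5061293477260227e-03   4   2   2   2
-4.7599901968538520e-02   4   2   3   1
 6.1518087356734346e-04   4   2   3   3
 8.2575180073656593e-02   4   2   4   2
-5.7584713707426537e-02   4   3   2   1
-4.8896958644744602e-02   4   3   3   2
-1.9978375154639013e-02   4   3   4   1
 1.0354513194223589e-01   4   3   4   3
 2.6346236512003912e-01   4   4   1   1
 2.3269274179353600e-01   4   4   2   2
-3.2115740512577103e-02   4   4   3   1
 2.6393409941952295e-01   4   4   3   3
 1.1613512007275510e-03   4   4   4   2
 2.6813124404069005e-01   4   4   4   4
 1.0408362028889021e-02   5   1   1   1
 2.8324867438394283e-02   5   1   2   2
 2.3556391238839472e-02   5   1   3   1
-1.8156023114026483e-02   5   1   3   3
 4.9774398460242272e-02   5   1   4   2
-1.8589139125565167e-02   5   1   4   4
 6.1987690148522727e-02   5   1   5   1
 2.7975491411120219e-02   5   2   2   1
-9.2484022799741335e-03   5   2   3   2
 6.2635534096742662e-02   5   2   4   1
 6.0803773511769674e-02   5   2   4   3
 1.1698903322832088e-01   5   2   5   2
 5.2712675496093847e-02   5   3   1   1
-3.0303414455385065e-03   5   3   2   2
-4.7949372901656323e-02   5   3   3   1
 2.5519411604179960e-03   5   3   3   3
 8.3297156432727504e-02   5   3   4   2
 1.3464925852160955e-03   5   3   4   4
 5.0380415828433368e-02   5   3   5   1
 8.5293739668590399e-02   5   3   5   3
 9.7011380524673327e-02   5   4   2   1
 1.1463900272157276e-01   5   4   3   2
-1.8618844340666046e-02   5   4   4   1
-5.0196486999819767e-02   5   4   4   3
-1.0821790495906850e-02   5   4   5   2
 1.1757018389457964e-01   5   4   5   4
 2.2952973123435993e-01   5   5   1   1
 2.8468250244210574e-01   5   5   2   2
 5.4355489068879402e-02   5   5   3   1
 2.3740350758750126e-01   5   5   3   3
-5.2416509977589541e-03   5   5   4   2
 2.3908221596596016e-01   5   5   4   4
 2.8562169314219610e-02   5   5   5   1
-3.8664996865864962e-03   5   5   5   3
 2.9344167436671831e-01   5   5   5   5
-7.7663030159718174e-04   6   1   2   1
 2.0497154097504487e-02   6   1   3   2
-3.4360477608248403e-02   6   1   4   1
 7.5440425626504631e-02   6   1   4   3
 5.3622098487604186e-02   6   1   5   2
 2.0283154739085669e-02   6   1   5   4
 8.9940409217483877e-02   6   1   6   1
 1.1554424423841449e-02   6   2   1   1
 2.9381611006753378e-02   6   2   2   2
 2.3354268672369314e-02   6   2   3   1
-1.6807944336219474e-02   6   2   3   3
 5.0297350165558856e-02   6   2   4   2
-1.8596798305571802e-02   6   2   4   4
 6.2500080106029948e-02   6   2   5   1
 5.1863095138355367e-02   6   2   5   3
 2.9671395928875282e-02   6   2   5   5
 6.3754098795579139e-02   6   2   6   2
 4.0511017994468282e-02   6   3   2   1
-1.6911085244114780e-02   6   3   3   2
 9.6889844996386199e-02   6   3   4   1
-1.9590483970152957e-02   6   3   4   3
 6.4924049418923768e-02   6   3   5   2
-1.8796155046546283e-02   6   3   5   4
-3.3670895486467095e-02   6   3   6   1
 9.9342150721056746e-02   6   3   6   3
-6.5192970390992352e-02   6   4   1   1
 5.3879919223232590e-02   6   4   2   2
 1.1577051117475201e-01   6   4   3   1
-3.1837861550809955e-02   6   4   3   3
-4.9968365129679775e-02   6   4   4   2
-3.3362080560937465e-02   6   4   4   4
 2.3359449722163372e-02   6   4   5   1
-5.0317477637477168e-02   6   4   5   3
 5.6420603817938703e-02   6   4   5   5
 2.3350837984752040e-02   6   4   6   2
 1.2054815940562080e-01   6   4   6   4
 1.1831271385929377e-01   6   5   2   1
 1.0087048401970668e-01   6   5   3   2
 4.0631003055283624e-02   6   5   4   1
-6.0579235740291504e-02   6   5   4   3
 2.8975077988680920e-02   6   5   5   2
 1.0224803611979183e-01   6   5   5   4
-8.9192716167485725e-04   6   5   6   1
 4.2558555162107999e-02   6   5   6   3
 1.2528318346426995e-01   6   5   6   5
 3.0087153547041562e-01   6   6   1   1
 2.3335384170486448e-01   6   6   2   2
-6.4330114284447931e-02   6   6   3   1
 2.7081149400757815e-01   6   6   3   3
 5.2937040473249833e-02   6   6   4   2
 2.7371059988224344e-01   6   6   4   4
 1.1270099677064972e-02   6   6   5   1
 5.5164024889030237e-02   6   6   5   3
 2.3975156694169494e-01   6   6   5   5
 1.2744322548745092e-02   6   6   6   2
-6.7424490855666749e-02   6   6   6   4
 3.1431736044123504e-01   6   6   6   6
-1.3599842362839387e+00   1   1   0   0
-1.2455768732040253e+00   2   2   0   0
 8.3557132864804956e-02   3   1   0   0
-1.2413162666972728e+00   3   3   0   0
-1.0841525709878584e-01   4   2   0   0
-1.1986473439801728e+00   4   4   0   0
-5.0719932144066088e-02   5   1   0   0
-8.7608620355301287e-02   5   3   0   0
-1.1200973081211223e+00   5   5   0   0
-3.6562286720465499e-02   6   2   0   0
 8.2648214051583443e-02   6   4   0   0
-1.1759703273488085e+00   6   6   0   0
 2.3019208674280498e+00   0   0   0   0
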