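 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6574622422127780e+00   1   1   1   1
 1.2321059348181079e-01   2   1   1   1
 1.6504634132547560e-02   2   1   2   1
 3.9359779194631767e-01   2   2   1   1
-8.4890711711045081e-03   2   2   2   1
 5.0130060743678972e-01   2   2   2   2
-1.3646523554185258e-01   3   1   1   1
-1.1945408478107461e-02   3   1   2   1
-1.8473304975351938e-02   3   1   2   2
 2.1317599978209461e-02   3   1   3   1
-9.5575112418718172e-03   3   2   1   1
-4.0499932147958113e-03   3   2   2   1
 4.5374415113704596e-02   3   2   2   2
-2.8946661765096092e-04   3   2   3   1
 1.1360015242912011e-02   3   2   3   2
 3.9612382042365096e-01   3   3   1   1
 1.2414085835783161e-02   3   3   2   1
 2.2996637253480601e-01   3   3   2   2
 2.1876722016305719e-03   3   3   3   1
-4.8259003087610317e-03   3   3   3   2
 3.3948505350757785e-01   3   3   3   3
 9.8216933424611144e-03   4   1   4   1
-7.6800508866748203e-03   4   2   4   1
 2.4577789372983466e-02   4   2   4   2
 1.0234202297933877e-02   4   3   4   1
-1.9183383446798975e-02   4   3   4   2
 4.1396458755666027e-02   4   3   4   3
 3.9629085295797373e-01   4   4   1   1
 4.8587015882071765e-03   4   4   2   1
 2.8018438709305782e-01   4   4   2   2
-4.8921586052860329e-03   4   4   3   1
-3.7952116343215217e-03   4   4   3   2
 2.8240041795174814e-01   4   4   3   3
 3.1294546903540316e-01   4   4   4   4
 9.8216933424611144e-03   5   1   5   1
-7.6800508866748203e-03   5   2   5   1
 2.4577789372983466e-02   5   2   5   2
 1.0234202297933877e-02   5   3   5   1
-1.9183383446798975e-02   5   3   5   2
 4.1396458755666027e-02   5   3   5   3
 1.6869136896862858e-02   5   4   5   4
 3.9629085295797373e-01   5   5   1   1
 4.8587015882071696e-03   5   5   2   1
 2.8018438709305782e-01   5   5   2   2
-4.8921586052860233e-03   5   5   3   1
-3.7952116343215000e-03   5   5   3   2
 2.8240041795174808e-01   5   5   3   3
 2.7920719524167742e-01   5   5   4   4
 3.1294546903540316e-01   5   5   5   5
 3.0212250241646518e-02   6   1   1   1
 6.8015320711598687e-03   6   1   2   1
-4.7209398046202311e-03   6   1   2   2
 1.5514680626574812e-04   6   1   3   1
-6.3235830506500914e-04   6   1   3   2
 8.4238239403615217e-03   6   1   3   3
-3.1416962354051473e-04   6   1   4   4
-3.1416962354051473e-04   6   1   5   5
 5.6898545446505532e-03   6   1   6   1
 1.2857543538194658e-02   6   2   1   1
 7.0175288515811366e-03   6   2   2   1
-1.3820121838009733e-01   6   2   2   2
 2.3575713911504160e-03   6   2   3   1
-3.2536538052639161e-02   6   2   3   2
 5.8507691366936560e-03   6   2   3   3
 4.9827980072705324e-03   6   2   4   4
 4.9827980072705315e-03   6   2   5   5
-1.0780672856910037e-03   6   2   6   1
 1.2225465610585108e-01   6   2   6   2
 1.7447566390722313e-02   6   3   1   1
 5.0480793511810829e-03   6   3   2   1
-5.0650863891369476e-02   6   3   2   2
 4.6184725919492624e-03   6   3   3   1
-7.5905885972354552e-03   6   3   3   2
 3.6149146068912570e-02   6   3   3   3
 6.7669198635525094e-04   6   3   4   4
 6.7669198635525094e-04   6   3   5   5
 3.8962336876236709e-03   6   3   6   1
 3.0393662392717041e-02   6   3   6   2
 2.6309103767057265e-02   6   3   6   3
-5.7829644481812003e-03   6   4   4   1
 1.9308187980346433e-02   6   4   4   2
-1.3904809674740937e-02   6   4   4   3
 1.9051122118143301e-02   6   4   6   4
-5.7829644481812003e-03   6   5   5   1
 1.9308187980346433e-02   6   5   5   2
-1.3904809674740937e-02   6   5   5   3
 1.9051122118143297e-02   6   5   6   5
 3.6129763169503953e-01   6   6   1   1
-5.7346575953520018e-03   6   6   2   1
 4.5986707058716680e-01   6   6   2   2
-1.1476761181047923e-02   6   6   3   1
 4.0960517693565297e-02   6   6   3   2
 2.4245634318609516e-01   6   6   3   3
 2.7012780334011260e-01   6   6   4   4
 2.7012780334011255e-01   6   6   5   5
-8.1133178171847716e-04   6   6   6   1
-1.4607213952189008e-01   6   6   6   2
-4.2966276890912453e-02   6   6   6   3
 4.5693451312229244e-01   6   6   6   6
-4.7741268635204621e+00   1   1   0   0
-1.1472152239591249e-01   2   1   0   0
-1.5731904277863937e+00   2   2   0   0
 1.6936185236528689e-01   3   1   0   0
-3.8204801017316790e-02   3   2   0   0
-1.1400032689370421e+00   3   3   0   0
-1.1552760240287809e+00   4   4   0   0
-1.1552760240287809e+00   5   5   0   0
-1.3752841700009809e-02   6   1   0   0
 1.1928766335876950e-01   6   2   0   0
 3.4025203906842529e-02   6   3   0   0
-9.1746742144915572e-01   6   6   0   0
 1.1339511662207142e+00   0   0   0   0
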