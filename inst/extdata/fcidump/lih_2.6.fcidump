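 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6596591141029848e+00   1   1   1   1
 9.8552231461584525e-02   2   1   1   1
 9.8907469661352609e-03   2   1   2   1
 2.8636209929224204e-01   2   2   1   1
-1.2166719105489558e-03   2   2   2   1
 4.2298798289917583e-01   2   2   2   2
-1.4289979387081961e-01   3   1   1   1
-1.1174370214457496e-02   3   1   2   1
-8.9073928339515971e-03   3   1   2   2
 2.1874578393340612e-02   3   1   3   1
-4.5507691190636072e-02   3   2   1   1
-2.5294726029979060e-03   3   2   2   1
 7.3197786398977852e-02   3   2   2   2
 6.5265782873388160e-04   3   2   3   1
 3.6569447935037441e-02   3   2   3   2
 3.8210198923363187e-01   3   3   1   1
 7.8365087273396215e-03   3   3   2   1
 2.1435671842092063e-01   3   3   2   2
 4.6258016969420101e-05   3   3   3   1
-1.8486851179685550e-02   3   3   3   2
 3.1397947543044907e-01   3   3   3   3
 9.7922522713154107e-03   4   1   4   1
-7.4154044816674182e-03   4   2   4   1
 2.0919728562460493e-02   4   2   4   2
 1.0472458835543914e-02   4   3   4   1
-2.2097694870629542e-02   4   3   4   2
 4.1232075248698187e-02   4   3   4   3
 3.9634800900467226e-01   4   4   1   1
 3.4756081885626592e-03   4   4   2   1
 2.2746499792635869e-01   4   4   2   2
-5.0700624084583975e-03   4   4   3   1
-2.3920549586173824e-02   4   4   3   2
 2.7477349922325595e-01   4   4   3   3
 3.1294546903540249e-01   4   4   4   4
 9.7922522713154176e-03   5   1   5   1
-7.4154044816674234e-03   5   2   5   1
 2.0919728562460507e-02   5   2   5   2
 1.0472458835543919e-02   5   3   5   1
-2.2097694870629552e-02   5   3   5   2
 4.1232075248698215e-02   5   3   5   3
 1.6869136896862837e-02   5   4   5   4
 3.9634800900467254e-01   5   5   1   1
 3.4756081885626727e-03   5   5   2   1
 2.2746499792635885e-01   5   5   2   2
-5.0700624084584157e-03   5   5   3   1
-2.3920549586173852e-02   5   5   3   2
 2.7477349922325611e-01   5   5   3   3
 2.7920719524167709e-01   5   5   4   4
 3.1294546903540299e-01   5   5   5   5
-6.1757909051177097e-02   6   1   1   1
-8.2042512204192168e-03   6   1   2   1
 6.5591342629164068e-03   6   1   2   2
 3.8258066053695077e-03   6   1   3   1
 3.0575448750138979e-03   6   1   3   2
-1.1129834030947403e-02   6   1   3   3
-1.5887839161398568e-03   6   1   4   4
-1.5887839161398576e-03   6   1   5   5
 1.0024193531797015e-02   6   1   6   1
-9.0731678669122559e-02   6   2   1   1
-6.1683080320454309e-04   6   2   2   1
 1.0002834275830579e-01   6   2   2   2
 5.0349851027251336e-03   6   2   3   1
 5.8776266814248988e-02   6   2   3   2
-1.2125498295210700e-02   6   2   3   3
-4.6343428825668886e-02   6   2   4   4
-4.6343428825668921e-02   6   2   5   5
-2.2598514412909354e-03   6   2   6   1
 1.3144735990857395e-01   6   2   6   2
-3.2986092122358424e-02   6   3   1   1
-2.1260541362675533e-03   6   3   2   1
 6.9507247661910410e-02   6   3   2   2
-3.8229931034887915e-03   6   3   3   1
 3.1002161610653639e-02   6   3   3   2
-3.6928662678139282e-02   6   3   3   3
-1.4874902930603026e-02   6   3   4   4
-1.4874902930603036e-02   6   3   5   5
 5.1760887333844544e-03   6   3   6   1
 4.7895752536775138e-02   6   3   6   2
 4.2676135708426634e-02   6   3   6   3
 5.0445993052412588e-03   6   4   4   1
-1.6671120370587003e-02   6   4   4   2
 9.5568721730269514e-03   6   4   4   3
 1.7808892150718188e-02   6   4   6   4
 5.0445993052412631e-03   6   5   5   1
-1.6671120370587014e-02   6   5   5   2
 9.5568721730269601e-03   6   5   5   3
 1.7808892150718205e-02   6   5   6   5
 3.4285933026051102e-01   6   6   1   1
 8.3435818020844235e-05   6   6   2   1
 3.8679834089388321e-01   6   6   2   2
-9.4872984959689464e-03   6   6   3   1
 5.1787038651985862e-02   6   6   3   2
 2.4250213232029727e-01   6   6   3   3
 2.5125929199372776e-01   6   6   4   4
 2.5125929199372793e-01   6   6   5   5
 5.3310941346426388e-03   6   6   6   1
 6.7223684279223664e-02   6   6   6   2
 4.7234260061403494e-02   6   6   6   3
 3.7662304001398106e-01   6   6   6   6
-4.6009635422863608e+00   1   1   0   0
-9.7335559467229521e-02   2   1   0   0
-1.1876902044196085e+00   2   2   0   0
 1.5818510696415095e-01   3   1   0   0
 6.6432251523030963e-03   3   2   0   0
-1.0707457373730065e+00   3   3   0   0
-1.0616954567928005e+00   4   4   0   0
-1.0616954567928012e+00   5   5   0   0
 4.8022809601747235e-02   6   1   0   0
 7.3230762879569963e-02   6   2   0   0
-1.0440237871286794e-02   6   3   0   0
-1.0219581399767677e+00   6   6   0   0
 6.1058908950346147e-01   0   0   0   0
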