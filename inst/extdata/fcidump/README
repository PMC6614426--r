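STO-3G molecular-orbital integrals (Molpro-style FCIDUMP) for the test
molecules, in chemists' notation with 1-based indices and the nuclear
repulsion on the trailing all-zero index line.

Files: <molecule>_<R>.fcidump with R the bond length in Angstrom
(for beh2 the common Be-H distance of the linear molecule; for h6 the
common adjacent H-H spacing of the collinear chain).

Provenance: generated at packaging time by tools/make_fixtures.py in the
source repository -- a standalone numpy/scipy program implementing
McMurchie-Davidson Gaussian integrals over the standard STO-3G basis
(universal 3-Gaussian contractions, Slater zeta scaling: H 1.24;
Li 2.69/0.80; Be 3.68/1.15), restricted Hartree-Fock with DIIS converged
to 1e-12, and the AO->MO transformation to canonical orbitals ordered by
orbital energy.  Validation against literature values at generation time:
H2 @0.7414 A: E_RHF = -1.1166844, E_FCI = -1.1372702;
LiH @1.5949 A: E_RHF = -7.8620270, E_FCI = -7.8824034.
Every 6-orbital file was additionally checked by an independent
determinant-basis FCI in the generator before being written.
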