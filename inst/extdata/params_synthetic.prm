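* Synthetic CHARMM-format non-bonded parameter file for the atom types used
* by the bundled residue templates. Epsilon (kcal/mol, printed negative per
* CHARMM convention) and Rmin/2 (Angstrom) follow standard protein
* force-field values; assembled for this package, not extracted from a
* distributed force-field release.
*

NONBONDED nbxmod  5 atom cdiel shift vatom vdistance vswitch -
cutnb 14.0 ctofnb 12.0 ctonnb 10.0 eps 1.0 e14fac 1.0 wmin 1.5

!atom  ignored    epsilon      Rmin/2
C      0.000000  -0.110000     2.000000
CA     0.000000  -0.070000     1.992400
CC     0.000000  -0.070000     2.000000
CPH1   0.000000  -0.050000     1.800000
CPH2   0.000000  -0.050000     1.800000
CPT    0.000000  -0.099000     1.860000
CY     0.000000  -0.073000     1.990000
CT1    0.000000  -0.020000     2.275000
CT2    0.000000  -0.055000     2.175000
CT3    0.000000  -0.080000     2.060000
H      0.000000  -0.046000     0.224500
HA     0.000000  -0.022000     1.320000
HB     0.000000  -0.022000     1.320000
HC     0.000000  -0.046000     0.224500
HP     0.000000  -0.030000     1.358200
HR1    0.000000  -0.046000     0.900000
HR2    0.000000  -0.046000     0.700000
HR3    0.000000  -0.007800     1.468000
HS     0.000000  -0.100000     0.450000
N      0.000000  -0.200000     1.850000
NC2    0.000000  -0.200000     1.850000
NH1    0.000000  -0.200000     1.850000
NH2    0.000000  -0.200000     1.850000
NH3    0.000000  -0.200000     1.850000
NR1    0.000000  -0.200000     1.850000
NR2    0.000000  -0.200000     1.850000
NR3    0.000000  -0.200000     1.850000
NY     0.000000  -0.200000     1.850000
O      0.000000  -0.120000     1.700000
OC     0.000000  -0.120000     1.700000
OH1    0.000000  -0.152100     1.770000
S      0.000000  -0.450000     2.000000

END
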