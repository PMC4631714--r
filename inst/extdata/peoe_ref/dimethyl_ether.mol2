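@<TRIPOS>MOLECULE
dimethyl_ether
 9 8 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9065   -0.0519    0.0376 C.3     1  UNL1        0.0361
      2 O           2.3275   -0.0593    0.0133 O.3     1  UNL1       -0.3862
      3 C           2.8251   -0.4467   -1.2603 C.3     1  UNL1        0.0361
      4 H           0.5803    0.2517    1.0359 H       1  UNL1        0.0523
      5 H           0.5148   -1.0526   -0.1690 H       1  UNL1        0.0523
      6 H           0.5148    0.6643   -0.6912 H       1  UNL1        0.0523
      7 H           3.9176   -0.4350   -1.2218 H       1  UNL1        0.0523
      8 H           2.4947    0.2569   -2.0306 H       1  UNL1        0.0523
      9 H           2.4947   -1.4600   -1.5085 H       1  UNL1        0.0523
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     1     4    1
     4     1     5    1
     5     1     6    1
     6     3     7    1
     7     3     8    1
     8     3     9    1
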