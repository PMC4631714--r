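@<TRIPOS>MOLECULE
methanethiol
 6 5 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0641    0.0815    0.0381 C.3     1  UNL1       -0.0211
      2 S           2.8669    0.1494    0.0609 S.3     1  UNL1       -0.1817
      3 H           0.7128   -0.7027    0.7132 H       1  UNL1        0.0338
      4 H           0.7128   -0.1353   -0.9738 H       1  UNL1        0.0338
      5 H           0.6528    1.0412    0.3608 H       1  UNL1        0.0338
      6 H           3.0733   -1.1066   -0.3615 H       1  UNL1        0.1014
@<TRIPOS>BOND
     1     1     2    1
     2     1     3    1
     3     1     4    1
     4     1     5    1
     5     2     6    1
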