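@<TRIPOS>MOLECULE
propane
 11 10 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0111    0.1121    0.0261 C.3     1  UNL1       -0.0655
      2 C           2.5301    0.0839    0.0264 C.3     1  UNL1       -0.0588
      3 C           3.0626   -1.3391    0.0318 C.3     1  UNL1       -0.0655
      4 H           0.6504    1.1456    0.0220 H       1  UNL1        0.0230
      5 H           0.6095   -0.3845    0.9153 H       1  UNL1        0.0230
      6 H           0.6097   -0.3916   -0.8592 H       1  UNL1        0.0230
      7 H           2.9051    0.6174    0.9068 H       1  UNL1        0.0260
      8 H           2.9052    0.6105   -0.8581 H       1  UNL1        0.0260
      9 H           2.7246   -1.8807    0.9210 H       1  UNL1        0.0230
     10 H           4.1571   -1.3350    0.0319 H       1  UNL1        0.0230
     11 H           2.7247   -1.8875   -0.8533 H       1  UNL1        0.0230
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     1     4    1
     4     1     5    1
     5     1     6    1
     6     2     7    1
     7     2     8    1
     8     3     9    1
     9     3    10    1
    10     3    11    1
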