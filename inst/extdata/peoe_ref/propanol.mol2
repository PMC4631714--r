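@<TRIPOS>MOLECULE
propanol
 12 11 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9556   -0.1010    0.0036 C.3     1  UNL1       -0.0632
      2 C           2.4732   -0.0796   -0.0176 C.3     1  UNL1       -0.0326
      3 C           3.0071    0.9014   -1.0516 C.3     1  UNL1        0.0440
      4 O           4.4278    0.8903   -1.0396 O.3     1  UNL1       -0.3950
      5 H           0.5953   -0.8124    0.7530 H       1  UNL1        0.0230
      6 H           0.5543   -0.4004   -0.9700 H       1  UNL1        0.0230
      7 H           0.5538    0.8865    0.2516 H       1  UNL1        0.0230
      8 H           2.8583   -1.0840   -0.2303 H       1  UNL1        0.0285
      9 H           2.8549    0.1854    0.9758 H       1  UNL1        0.0285
     10 H           2.6657    1.9212   -0.8470 H       1  UNL1        0.0557
     11 H           2.6761    0.6247   -2.0575 H       1  UNL1        0.0557
     12 H           4.7151    1.1623   -0.1509 H       1  UNL1        0.2094
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     3     4    1
     4     1     5    1
     5     1     6    1
     6     1     7    1
     7     2     8    1
     8     2     9    1
     9     3    10    1
    10     3    11    1
    11     4    12    1
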