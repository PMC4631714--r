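@<TRIPOS>MOLECULE
methanol
 6 5 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9684    0.0034   -0.0873 C.3     1  UNL1        0.0330
      2 O           2.3842   -0.0013   -0.0970 O.3     1  UNL1       -0.3982
      3 H           0.6069    1.0324   -0.0193 H       1  UNL1        0.0521
      4 H           0.6069   -0.5783    0.7642 H       1  UNL1        0.0521
      5 H           0.6053   -0.4474   -1.0140 H       1  UNL1        0.0521
      6 H           2.6771    0.4043    0.7368 H       1  UNL1        0.2090
@<TRIPOS>BOND
     1     1     2    1
     2     1     3    1
     3     1     4    1
     4     1     5    1
     5     2     6    1
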