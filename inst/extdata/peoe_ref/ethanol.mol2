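@<TRIPOS>MOLECULE
ethanol
 9 8 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0661   -0.0749    0.0365 C.3     1  UNL1       -0.0418
      2 C           2.5803   -0.0724    0.0297 C.3     1  UNL1        0.0414
      3 O           3.0620    1.0042   -0.7608 O.3     1  UNL1       -0.3953
      4 H           0.6813   -0.8939    0.6506 H       1  UNL1        0.0252
      5 H           0.6741   -0.1827   -0.9802 H       1  UNL1        0.0252
      6 H           0.6806    0.8723    0.4280 H       1  UNL1        0.0252
      7 H           2.9718   -1.0098   -0.3772 H       1  UNL1        0.0554
      8 H           2.9673    0.0508    1.0454 H       1  UNL1        0.0554
      9 H           2.7224    0.8802   -1.6635 H       1  UNL1        0.2094
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     1     4    1
     4     1     5    1
     5     1     6    1
     6     2     7    1
     7     2     8    1
     8     3     9    1
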