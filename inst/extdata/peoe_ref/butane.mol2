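@<TRIPOS>MOLECULE
butane
 14 13 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9755   -0.0478   -0.0773 C.3     1  UNL1       -0.0653
      2 C           2.4945   -0.0583   -0.0845 C.3     1  UNL1       -0.0562
      3 C           3.0389   -1.2211   -0.9117 C.3     1  UNL1       -0.0562
      4 C           4.5584   -1.2325   -0.9174 C.3     1  UNL1       -0.0653
      5 H           0.6037    0.7909    0.5193 H       1  UNL1        0.0230
      6 H           0.5793   -0.9733    0.3535 H       1  UNL1        0.0230
      7 H           0.5795    0.0553   -1.0930 H       1  UNL1        0.0230
      8 H           2.8600   -0.1309    0.9465 H       1  UNL1        0.0263
      9 H           2.8601    0.8919   -0.4916 H       1  UNL1        0.0263
     10 H           2.6745   -1.1475   -1.9431 H       1  UNL1        0.0263
     11 H           2.6723   -2.1711   -0.5054 H       1  UNL1        0.0263
     12 H           4.9549   -0.3071   -1.3471 H       1  UNL1        0.0230
     13 H           4.9296   -2.0714   -1.5142 H       1  UNL1        0.0230
     14 H           4.9525   -1.3364    0.0986 H       1  UNL1        0.0230
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
    12     4    13    1
    13     4    14    1
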