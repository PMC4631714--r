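@<TRIPOS>MOLECULE
ethane
 8 7 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9376    0.0696   -0.0274 C.3     1  UNL1       -0.0681
      2 C           2.4497    0.0696   -0.0274 C.3     1  UNL1       -0.0681
      3 H           0.5533    0.6420   -0.8770 H       1  UNL1        0.0227
      4 H           0.5533    0.5192    0.8930 H       1  UNL1        0.0227
      5 H           0.5533   -0.9523   -0.0983 H       1  UNL1        0.0227
      6 H           2.8340    1.0915    0.0435 H       1  UNL1        0.0227
      7 H           2.8340   -0.3800   -0.9478 H       1  UNL1        0.0227
      8 H           2.8340   -0.5027    0.8222 H       1  UNL1        0.0227
@<TRIPOS>BOND
     1     1     2    1
     2     1     3    1
     3     1     4    1
     4     1     5    1
     5     2     6    1
     6     2     7    1
     7     2     8    1
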