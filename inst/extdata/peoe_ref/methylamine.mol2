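@<TRIPOS>MOLECULE
methylamine
 7 6 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0574    0.0354    0.0861 C.3     1  UNL1       -0.0188
      2 N           2.5093    0.0247    0.0953 N.3     1  UNL1       -0.3327
      3 H           0.6824    0.8160   -0.5819 H       1  UNL1        0.0386
      4 H           0.6748    0.2222    1.0933 H       1  UNL1        0.0386
      5 H           0.6748   -0.9309   -0.2539 H       1  UNL1        0.0386
      6 H           2.8531    0.9394    0.3848 H       1  UNL1        0.1180
      7 H           2.8531   -0.1202   -0.8531 H       1  UNL1        0.1180
@<TRIPOS>BOND
     1     1     2    1
     2     1     3    1
     3     1     4    1
     4     1     5    1
     5     2     6    1
     6     2     7    1
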