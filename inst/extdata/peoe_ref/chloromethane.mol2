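@<TRIPOS>MOLECULE
chloromethane
 5 4 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0896    0.0547    0.0133 C.3     1  UNL1        0.0110
      2 CL          2.8566    0.0547    0.0133 Cl      1  UNL1       -0.1291
      3 H           0.7326   -0.9498    0.2511 H       1  UNL1        0.0394
      4 H           0.7325    0.3509   -0.9754 H       1  UNL1        0.0394
      5 H           0.7325    0.7628    0.7643 H       1  UNL1        0.0394
@<TRIPOS>BOND
     1     1     2    1
     2     1     3    1
     3     1     4    1
     4     1     5    1
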