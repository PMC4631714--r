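@<TRIPOS>MOLECULE
fluoroethane
 8 7 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           0.9790   -0.0590    0.0716 C.3     1  UNL1       -0.0367
      2 C           2.4890   -0.0527    0.0733 C.3     1  UNL1        0.0874
      3 F           2.9327   -1.2934   -0.2592 F       1  UNL1       -0.2494
      4 H           0.5831    0.9255    0.3354 H       1  UNL1        0.0254
      5 H           0.6000   -0.7962    0.7861 H       1  UNL1        0.0254
      6 H           0.6000   -0.3401   -0.9158 H       1  UNL1        0.0254
      7 H           2.8830    0.1960    1.0624 H       1  UNL1        0.0612
      8 H           2.8830    0.6572   -0.6589 H       1  UNL1        0.0612
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     1     4    1
     4     1     5    1
     5     1     6    1
     6     2     7    1
     7     2     8    1
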