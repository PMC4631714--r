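@<TRIPOS>MOLECULE
isobutane
 14 13 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C           1.0196    0.0932    0.0139 C.3     1  UNL1       -0.0629
      2 C           2.5467    0.0970   -0.0096 C.3     1  UNL1       -0.0496
      3 C           3.0670   -1.0288   -0.9010 C.3     1  UNL1       -0.0629
      4 C           3.0670    1.4465   -0.5003 C.3     1  UNL1       -0.0629
      5 H           0.6380   -0.8637    0.3852 H       1  UNL1        0.0232
      6 H           0.6082    0.2554   -0.9882 H       1  UNL1        0.0232
      7 H           0.6380    0.8840    0.6681 H       1  UNL1        0.0232
      8 H           2.9123   -0.0682    1.0109 H       1  UNL1        0.0293
      9 H           2.7256   -0.9050   -1.9344 H       1  UNL1        0.0232
     10 H           2.7163   -2.0026   -0.5435 H       1  UNL1        0.0232
     11 H           4.1619   -1.0471   -0.9065 H       1  UNL1        0.0232
     12 H           2.7256    1.6550   -1.5200 H       1  UNL1        0.0232
     13 H           4.1619    1.4656   -0.4999 H       1  UNL1        0.0232
     14 H           2.7163    2.2578    0.1461 H       1  UNL1        0.0232
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     2     4    1
     4     1     5    1
     5     1     6    1
     6     1     7    1
     7     2     8    1
     8     3     9    1
     9     3    10    1
    10     3    11    1
    11     4    12    1
    12     4    13    1
    13     4    14    1
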