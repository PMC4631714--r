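Reference MOL2 fixtures for the PEOE charge assigner.

Twelve small sp3 organic molecules; 3D coordinates generated and Gasteiger
partial charges assigned once with Open Babel 3.1.0
(obabel -:"<smiles>" --gen3d --partialcharge gasteiger). The charge column
is the frozen independent reference the test suite compares
assign_gasteiger() against (tolerance 0.01 e per atom).
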