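REMARK   1 SYNTHETIC 30-RESIDUE HELICAL C-ALPHA TRACE (TEST FIXTURE, NOT A REAL PROTEIN)
ATOM      1  CA  ALA A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  GLY A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      3  CA  SER A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  LEU A   4       1.150  -1.992   4.500  1.00  0.00           C
ATOM      5  CA  VAL A   5       1.762   1.478   6.000  1.00  0.00           C
ATOM      6  CA  ALA A   6      -1.762   1.478   7.500  1.00  0.00           C
ATOM      7  CA  GLY A   7      -1.150  -1.992   9.000  1.00  0.00           C
ATOM      8  CA  SER A   8       2.161  -0.787  10.500  1.00  0.00           C
ATOM      9  CA  LEU A   9       0.399   2.265  12.000  1.00  0.00           C
ATOM     10  CA  VAL A  10      -2.300   0.000  13.500  1.00  0.00           C
ATOM     11  CA  ALA A  11       0.399  -2.265  15.000  1.00  0.00           C
ATOM     12  CA  GLY A  12       2.161   0.787  16.500  1.00  0.00           C
ATOM     13  CA  SER A  13      -1.150   1.992  18.000  1.00  0.00           C
ATOM     14  CA  LEU A  14      -1.762  -1.478  19.500  1.00  0.00           C
ATOM     15  CA  VAL A  15       1.762  -1.478  21.000  1.00  0.00           C
ATOM     16  CA  ALA A  16       1.150   1.992  22.500  1.00  0.00           C
ATOM     17  CA  GLY A  17      -2.161   0.787  24.000  1.00  0.00           C
ATOM     18  CA  SER A  18      -0.399  -2.265  25.500  1.00  0.00           C
ATOM     19  CA  LEU A  19       2.300  -0.000  27.000  1.00  0.00           C
ATOM     20  CA  VAL A  20      -0.399   2.265  28.500  1.00  0.00           C
ATOM     21  CA  ALA A  21      -2.161  -0.787  30.000  1.00  0.00           C
ATOM     22  CA  GLY A  22       1.150  -1.992  31.500  1.00  0.00           C
ATOM     23  CA  SER A  23       1.762   1.478  33.000  1.00  0.00           C
ATOM     24  CA  LEU A  24      -1.762   1.478  34.500  1.00  0.00           C
ATOM     25  CA  VAL A  25      -1.150  -1.992  36.000  1.00  0.00           C
ATOM     26  CA  ALA A  26       2.161  -0.787  37.500  1.00  0.00           C
ATOM     27  CA  GLY A  27       0.399   2.265  39.000  1.00  0.00           C
ATOM     28  CA  SER A  28      -2.300  -0.000  40.500  1.00  0.00           C
ATOM     29  CA  LEU A  29       0.399  -2.265  42.000  1.00  0.00           C
ATOM     30  CA  VAL A  30       2.161   0.787  43.500  1.00  0.00           C
TER
END
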