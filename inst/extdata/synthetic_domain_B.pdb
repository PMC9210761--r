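REMARK   1 SYNTHETIC 24-RESIDUE HELICAL C-ALPHA TRACE (TEST FIXTURE, NOT A REAL PROTEIN)
ATOM      1  CA  ALA A   1       1.243   1.935   0.000  1.00  0.00           C
ATOM      2  CA  GLY A   2      -2.122   0.888   1.500  1.00  0.00           C
ATOM      3  CA  SER A   3      -0.506  -2.244   3.000  1.00  0.00           C
ATOM      4  CA  LEU A   4       2.297  -0.109   4.500  1.00  0.00           C
ATOM      5  CA  VAL A   5      -0.292   2.281   6.000  1.00  0.00           C
ATOM      6  CA  ALA A   6      -2.196  -0.684   7.500  1.00  0.00           C
ATOM      7  CA  GLY A   7       1.055  -2.044   9.000  1.00  0.00           C
ATOM      8  CA  SER A   8       1.830   1.394  10.500  1.00  0.00           C
ATOM      9  CA  LEU A   9      -1.690   1.560  12.000  1.00  0.00           C
ATOM     10  CA  VAL A  10      -1.243  -1.935  13.500  1.00  0.00           C
ATOM     11  CA  ALA A  11       2.122  -0.888  15.000  1.00  0.00           C
ATOM     12  CA  GLY A  12       0.506   2.244  16.500  1.00  0.00           C
ATOM     13  CA  SER A  13      -2.297   0.109  18.000  1.00  0.00           C
ATOM     14  CA  LEU A  14       0.292  -2.281  19.500  1.00  0.00           C
ATOM     15  CA  VAL A  15       2.196   0.684  21.000  1.00  0.00           C
ATOM     16  CA  ALA A  16      -1.055   2.044  22.500  1.00  0.00           C
ATOM     17  CA  GLY A  17      -1.830  -1.394  24.000  1.00  0.00           C
ATOM     18  CA  SER A  18       1.690  -1.560  25.500  1.00  0.00           C
ATOM     19  CA  LEU A  19       1.243   1.935  27.000  1.00  0.00           C
ATOM     20  CA  VAL A  20      -2.122   0.888  28.500  1.00  0.00           C
ATOM     21  CA  ALA A  21      -0.506  -2.244  30.000  1.00  0.00           C
ATOM     22  CA  GLY A  22       2.297  -0.109  31.500  1.00  0.00           C
ATOM     23  CA  SER A  23      -0.292   2.281  33.000  1.00  0.00           C
ATOM     24  CA  LEU A  24      -2.196  -0.684  34.500  1.00  0.00           C
TER
END
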