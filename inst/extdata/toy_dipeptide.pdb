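ATOM      1 N    ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2 CA   ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3 C    ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4 O    ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5 CB   ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C
ATOM      6 N    GLY A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      7 CA   GLY A   2       4.001   2.832   0.000  1.00  0.00           C
ATOM      8 C    GLY A   2       5.513   2.662   0.000  1.00  0.00           C
ATOM      9 O    GLY A   2       6.012   1.533   0.000  1.00  0.00           O
END
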