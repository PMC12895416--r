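ATOM      1 HH31 ACE A   1       1.551   1.424  -0.890  1.00  0.00           H
ATOM      2  CH3 ACE A   1       2.000   1.000   0.000  1.00  0.00           C
ATOM      3 HH32 ACE A   1       1.551   1.424   0.890  1.00  0.00           H
ATOM      4 HH33 ACE A   1       1.737  -0.060   0.000  1.00  0.00           H
ATOM      5  C   ACE A   1       3.500   1.000   0.000  1.00  0.00           C
ATOM      6  O   ACE A   1       4.150   2.045   0.000  1.00  0.00           O
ATOM      7  N   ALA A   2       4.145  -0.160   0.000  1.00  0.00           N
ATOM      8  H   ALA A   2       3.645  -1.028   0.000  1.00  0.00           H
ATOM      9  CA  ALA A   2       5.597  -0.252   0.000  1.00  0.00           C
ATOM     10  HA  ALA A   2       5.950   0.250   0.890  1.00  0.00           H
ATOM     11  CB  ALA A   2       6.099  -1.698   0.100  1.00  0.00           C
ATOM     12  HB1 ALA A   2       5.720  -2.270  -0.740  1.00  0.00           H
ATOM     13  HB2 ALA A   2       7.185  -1.720   0.110  1.00  0.00           H
ATOM     14  HB3 ALA A   2       5.720  -2.150   1.020  1.00  0.00           H
ATOM     15  C   ALA A   2       6.170   0.480  -1.210  1.00  0.00           C
ATOM     16  O   ALA A   2       5.490   0.720  -2.200  1.00  0.00           O
ATOM     17  N   NME A   3       7.470   0.790  -1.170  1.00  0.00           N
ATOM     18  H   NME A   3       7.990   0.570  -0.340  1.00  0.00           H
ATOM     19  CH3 NME A   3       8.130   1.490  -2.260  1.00  0.00           C
ATOM     20 HH31 NME A   3       7.460   2.250  -2.650  1.00  0.00           H
ATOM     21 HH32 NME A   3       9.030   1.960  -1.880  1.00  0.00           H
ATOM     22 HH33 NME A   3       8.400   0.790  -3.050  1.00  0.00           H
END
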