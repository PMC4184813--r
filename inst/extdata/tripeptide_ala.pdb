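ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  H   ALA A   1      -0.491   0.481   0.740  1.00  0.00           H  
ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C  
ATOM      4  HA  ALA A   1       1.804   0.506  -0.901  1.00  0.00           H  
ATOM      5  CB  ALA A   1       1.988   0.766   1.202  1.00  0.00           C  
ATOM      6  HB1 ALA A   1       3.078   0.757   1.188  1.00  0.00           H  
ATOM      7  HB2 ALA A   1       1.633   1.796   1.163  1.00  0.00           H  
ATOM      8  HB3 ALA A   1       1.633   0.295   2.119  1.00  0.00           H  
ATOM      9  C   ALA A   1       2.009  -1.422   0.000  1.00  0.00           C  
ATOM     10  O   ALA A   1       2.910  -1.749  -0.773  1.00  0.00           O  
ATOM     11  N   ALA A   2       1.463  -2.263   0.872  1.00  0.00           N  
ATOM     12  H   ALA A   2       0.727  -1.933   1.480  1.00  0.00           H  
ATOM     13  CA  ALA A   2       1.899  -3.650   0.974  1.00  0.00           C  
ATOM     14  HA  ALA A   2       2.948  -3.663   1.273  1.00  0.00           H  
ATOM     15  CB  ALA A   2       1.098  -4.381   2.041  1.00  0.00           C  
ATOM     16  HB1 ALA A   2       1.435  -5.415   2.105  1.00  0.00           H  
ATOM     17  HB2 ALA A   2       1.243  -3.892   3.004  1.00  0.00           H  
ATOM     18  HB3 ALA A   2       0.040  -4.360   1.779  1.00  0.00           H  
ATOM     19  C   ALA A   2       1.768  -4.370  -0.364  1.00  0.00           C  
ATOM     20  O   ALA A   2       2.689  -5.059  -0.802  1.00  0.00           O  
ATOM     21  N   ALA A   3       0.618  -4.205  -1.008  1.00  0.00           N  
ATOM     22  H   ALA A   3      -0.100  -3.627  -0.595  1.00  0.00           H  
ATOM     23  CA  ALA A   3       0.364  -4.838  -2.297  1.00  0.00           C  
ATOM     24  HA  ALA A   3       0.397  -5.919  -2.164  1.00  0.00           H  
ATOM     25  CB  ALA A   3      -1.021  -4.468  -2.806  1.00  0.00           C  
ATOM     26  HB1 ALA A   3      -1.195  -4.948  -3.769  1.00  0.00           H  
ATOM     27  HB2 ALA A   3      -1.773  -4.804  -2.091  1.00  0.00           H  
ATOM     28  HB3 ALA A   3      -1.089  -3.386  -2.922  1.00  0.00           H  
ATOM     29  C   ALA A   3       1.421  -4.443  -3.323  1.00  0.00           C  
ATOM     30  O   ALA A   3       1.961  -5.294  -4.030  1.00  0.00           O  
END   
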