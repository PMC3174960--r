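HEADER    SYNTHETIC TRIPEPTIDE                    01-JAN-26   TOY1
REMARK   2 RESOLUTION.    1.20 ANGSTROMS.
REMARK   3   R VALUE            (WORKING SET) : 0.150
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 20.00              
ATOM      3  C   ALA A   1       2.005   1.424   0.000  1.00 20.00              
ATOM      4  O   ALA A   1       1.365   2.330  -0.534  1.00 20.00              
ATOM      5  N   ALA A   2       3.158   1.632   0.626  1.00 20.00              
ATOM      6  CA  ALA A   2       3.791   2.945   0.650  1.00 20.00              
ATOM      7  C   ALA A   2       4.171   3.394  -0.756  1.00 20.00              
ATOM      8  O   ALA A   2       4.462   2.559  -1.613  1.00 20.00              
ATOM      9  N   ALA A   3       4.132   4.698  -1.009  1.00 20.00              
ATOM     10  CA  ALA A   3       4.517   5.239  -2.307  1.00 20.00              
ATOM     11  C   ALA A   3       5.987   4.959  -2.602  1.00 20.00              
ATOM     12  O   ALA A   3       6.803   4.910  -1.681  1.00 20.00              
END
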