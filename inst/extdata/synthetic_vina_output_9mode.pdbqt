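MODEL 1
REMARK VINA RESULT:      -8.2      0.000      0.000
ROOT
ATOM      1 C1  LIG A   1      14.113  10.306   9.089  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      11.899  13.213   7.682  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1      14.535  11.716  14.055  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1       9.812  15.915  14.860  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       5.833  11.164   7.600  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1      11.908  11.147   0.031  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 2
REMARK VINA RESULT:      -7.9      1.100      1.800
ROOT
ATOM      1 C1  LIG A   1       2.679  15.960   7.080  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1       4.656  11.484  11.644  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1      15.686  10.709   7.228  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1       4.711  13.380   6.080  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1      11.366  14.115  11.105  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1       8.173  13.515   2.849  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 3
REMARK VINA RESULT:      -7.9      2.200      3.600
ROOT
ATOM      1 C1  LIG A   1       7.647   9.447   0.757  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      10.108  12.618   6.917  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1      12.274   9.820   3.895  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1      11.298   9.566  12.332  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       8.706  13.967   8.966  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1       7.648  16.727   9.929  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 4
REMARK VINA RESULT:      -7.5      3.300      5.400
ROOT
ATOM      1 C1  LIG A   1      10.269  12.830  10.038  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      10.269   3.021   8.855  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1       8.898  12.556   9.745  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1      14.199   9.818  11.908  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1      11.008  15.116  10.762  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1      12.163   8.871   7.729  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 5
REMARK VINA RESULT:      -7.1      4.400      7.200
ROOT
ATOM      1 C1  LIG A   1      11.871   9.139   6.372  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      11.743  14.305   9.391  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1       7.343   8.701  12.538  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1      10.774  12.265   7.637  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       6.417  13.836   7.349  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1       9.452  14.800  10.465  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 6
REMARK VINA RESULT:      -6.8      5.500      9.000
ROOT
ATOM      1 C1  LIG A   1      14.176  10.571   9.951  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      14.173   8.668   5.418  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1       6.605   7.622   8.240  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1      11.960  15.603  11.134  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       6.990  17.545   6.000  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1      10.317  10.733   7.633  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 7
REMARK VINA RESULT:      -6.4      6.600      10.800
ROOT
ATOM      1 C1  LIG A   1      10.565  12.357   7.925  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      10.324  10.544   6.487  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1       5.017  10.853   6.462  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1      18.106   7.914   8.412  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       5.519   7.589   8.374  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1       7.010  11.995   6.715  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 8
REMARK VINA RESULT:      -6.1      7.700      12.600
ROOT
ATOM      1 C1  LIG A   1       8.159   5.926   4.326  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1      10.539  13.703   6.521  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1      10.000  15.369  12.320  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1       6.709  11.648  11.604  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       8.591  11.843   7.742  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1       7.337  10.666   7.912  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
MODEL 9
REMARK VINA RESULT:      -5.7      8.800      14.400
ROOT
ATOM      1 C1  LIG A   1       8.758  15.340   6.557  1.00  0.00     0.012 C 
ATOM      2 C2  LIG A   1       8.700  14.091   4.831  1.00  0.00     0.012 C 
ATOM      3 O3  LIG A   1       9.878   7.345  11.502  1.00  0.00     0.012 OA
ATOM      4 N4  LIG A   1       9.179  10.596   4.285  1.00  0.00     0.012 N 
ATOM      5 C5  LIG A   1       9.977   9.599   6.400  1.00  0.00     0.012 C 
ATOM      6 H6  LIG A   1      13.863  11.473   4.785  1.00  0.00     0.012 HD
ENDROOT
TORSDOF 0
ENDMDL
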