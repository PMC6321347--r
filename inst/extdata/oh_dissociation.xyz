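3
frame 1
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.764277  0.590382  0.003140
3
frame 2
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.755618  0.589246 -0.007650
3
frame 3
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.751919  0.598933 -0.002196
3
frame 4
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.753280  0.587762  0.006658
3
frame 5
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.751868  0.588715 -0.001365
3
frame 6
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.757200  0.586669  0.005694
3
frame 7
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.756454  0.590288  0.005191
3
frame 8
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.766211  0.593864 -0.007190
3
frame 9
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.766052  0.587510  0.001632
3
frame 10
O    0.000000  0.000000  0.000000
H    0.758315  0.588692  0.000000
H   -0.757087  0.584674 -0.003896
3
frame 11
O    0.000000  0.000000  0.000000
H    0.878382  0.681902  0.000000
H   -0.765829  0.594682  0.004879
3
frame 12
O    0.000000  0.000000  0.000000
H    0.998448  0.775111  0.000000
H   -0.765657  0.598849  0.004665
3
frame 13
O    0.000000  0.000000  0.000000
H    1.118515  0.868321  0.000000
H   -0.757821  0.589055 -0.009972
3
frame 14
O    0.000000  0.000000  0.000000
H    1.238581  0.961530  0.000000
H   -0.753421  0.591470 -0.002101
3
frame 15
O    0.000000  0.000000  0.000000
H    1.358648  1.054740  0.000000
H   -0.765330  0.592069  0.007010
3
frame 16
O    0.000000  0.000000  0.000000
H    1.478714  1.147949  0.000000
H   -0.767726  0.582969  0.005587
3
frame 17
O    0.000000  0.000000  0.000000
H    1.598781  1.241159  0.000000
H   -0.766597  0.582981  0.005576
3
frame 18
O    0.000000  0.000000  0.000000
H    1.718848  1.334368  0.000000
H   -0.754483  0.582714  0.001010
3
frame 19
O    0.000000  0.000000  0.000000
H    1.838914  1.427578  0.000000
H   -0.759295  0.586341  0.004595
3
frame 20
O    0.000000  0.000000  0.000000
H    1.958981  1.520788  0.000000
H   -0.760394  0.596494  0.005381
3
frame 21
O    0.000000  0.000000  0.000000
H    2.079047  1.613997  0.000000
H   -0.763660  0.594947 -0.007333
3
frame 22
O    0.000000  0.000000  0.000000
H    2.199114  1.707207  0.000000
H   -0.754318  0.581445 -0.007754
3
frame 23
O    0.000000  0.000000  0.000000
H    2.319180  1.800416  0.000000
H   -0.752298  0.588856  0.009355
3
frame 24
O    0.000000  0.000000  0.000000
H    2.439247  1.893626  0.000000
H   -0.764806  0.586728  0.006775
3
frame 25
O    0.000000  0.000000  0.000000
H    2.559313  1.986835  0.000000
H   -0.759051  0.583433 -0.003726
3
frame 26
O    0.000000  0.000000  0.000000
H    2.679380  2.080045  0.000000
H   -0.766291  0.587022 -0.009649
3
frame 27
O    0.000000  0.000000  0.000000
H    2.799447  2.173255  0.000000
H   -0.768268  0.588428 -0.008586
3
frame 28
O    0.000000  0.000000  0.000000
H    2.919513  2.266464  0.000000
H   -0.760360  0.589985 -0.006231
3
frame 29
O    0.000000  0.000000  0.000000
H    3.039580  2.359674  0.000000
H   -0.769571  0.590796  0.004297
3
frame 30
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.751085  0.597385  0.007735
3
frame 31
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.760934  0.586734 -0.000418
3
frame 32
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.769002  0.586565 -0.009626
3
frame 33
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.752655  0.587729  0.005141
3
frame 34
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.769350  0.581208  0.008612
3
frame 35
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.763601  0.599587 -0.005765
3
frame 36
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.756936  0.588607 -0.004404
3
frame 37
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.762832  0.595015 -0.006791
3
frame 38
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.760393  0.596295 -0.008182
3
frame 39
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.769190  0.587467 -0.001198
3
frame 40
O    0.000000  0.000000  0.000000
H    3.159646  2.452883  0.000000
H   -0.766707  0.593710 -0.000590
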