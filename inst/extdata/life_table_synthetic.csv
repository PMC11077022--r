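sex,age,annual_mortality_probability
male,35,0.001725
male,36,0.001822
male,37,0.001925
male,38,0.002033
male,39,0.002148
male,40,0.002269
male,41,0.002441
male,42,0.002626
male,43,0.002824
male,44,0.003038
male,45,0.003268
male,46,0.003544
male,47,0.003843
male,48,0.004168
male,49,0.00452
male,50,0.004902
male,51,0.005302
male,52,0.005736
male,53,0.006205
male,54,0.006713
male,55,0.007262
male,56,0.00794
male,57,0.008681
male,58,0.009491
male,59,0.010377
male,60,0.011346
male,61,0.012376
male,62,0.013499
male,63,0.014725
male,64,0.016061
male,65,0.017519
male,66,0.01926
male,67,0.021175
male,68,0.02328
male,69,0.025594
male,70,0.028139
male,71,0.030999
male,72,0.03415
male,73,0.037621
male,74,0.041445
male,75,0.045657
male,76,0.050345
male,77,0.055515
male,78,0.061215
male,79,0.067501
male,80,0.074431
male,81,0.081617
male,82,0.089497
male,83,0.098137
male,84,0.107612
male,85,0.118001
male,86,0.128618
male,87,0.140191
male,88,0.152805
male,89,0.166554
male,90,0.18154
male,91,0.196875
male,92,0.213505
male,93,0.231541
male,94,0.251099
male,95,0.27231
male,96,0.291266
male,97,0.311541
male,98,0.333227
male,99,0.356423
male,100,0.381234
female,35,8e-04
female,36,0.000853
female,37,0.000909
female,38,0.000968
female,39,0.001032
female,40,0.0011
female,41,0.00117
female,42,0.001245
female,43,0.001325
female,44,0.00141
female,45,0.0015
female,46,0.001634
female,47,0.00178
female,48,0.001939
female,49,0.002112
female,50,0.0023
female,51,0.002516
female,52,0.002751
female,53,0.003009
female,54,0.003291
female,55,0.0036
female,56,0.00396
female,57,0.004357
female,58,0.004793
female,59,0.005272
female,60,0.0058
female,61,0.006402
female,62,0.007066
female,63,0.007798
female,64,0.008607
female,65,0.0095
female,66,0.010609
female,67,0.011848
female,68,0.013231
female,69,0.014775
female,70,0.0165
female,71,0.018596
female,72,0.020957
female,73,0.023619
female,74,0.026619
female,75,0.03
female,76,0.033989
female,77,0.038508
female,78,0.043628
female,79,0.049428
female,80,0.056
female,81,0.062244
female,82,0.069183
female,83,0.076897
female,84,0.085471
female,85,0.095
female,86,0.10609
female,87,0.118475
female,88,0.132306
female,89,0.147751
female,90,0.165
female,91,0.1814
female,92,0.199429
female,93,0.219251
female,94,0.241042
female,95,0.265
female,96,0.287746
female,97,0.312444
female,98,0.339261
female,99,0.368381
female,100,0.4
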