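time_ms,strain_pct
0,0.183348
13.3333,0.031247
26.6667,0.041051
40,0.105059
53.3333,0.152434
66.6667,0.412488
80,0.842097
93.3333,1.330097
106.6667,1.85726
120,2.303915
133.3333,2.799269
146.6667,3.075547
160,2.94839
173.3333,2.824914
186.6667,2.550554
200,1.873622
213.3333,0.674156
226.6667,-0.898763
240,-2.321271
253.3333,-3.694889
266.6667,-5.548665
280,-7.557818
293.3333,-9.239834
306.6667,-10.746215
320,-12.355542
333.3333,-13.989661
346.6667,-15.364693
360,-16.307193
373.3333,-16.807079
386.6667,-17.008003
400,-16.999874
413.3333,-17.118506
426.6667,-17.527083
440,-18.110177
453.3333,-18.753223
466.6667,-19.452754
480,-20.012547
493.3333,-20.500827
506.6667,-20.856064
520,-20.829465
533.3333,-20.691428
546.6667,-20.478127
560,-20.084424
573.3333,-19.657144
586.6667,-18.988878
600,-18.032464
613.3333,-16.949539
626.6667,-15.759277
640,-14.565282
653.3333,-13.276714
666.6667,-11.969293
680,-10.60723
693.3333,-9.092496
706.6667,-7.739073
720,-6.521994
733.3333,-5.264534
746.6667,-4.08666
760,-3.238312
773.3333,-2.498035
786.6667,-1.576345
800,-0.827626
813.3333,-0.334211
826.6667,0.050517
840,0.247055
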