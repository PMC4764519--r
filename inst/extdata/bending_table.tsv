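angle	energy
0	8.82
0.04908739	8.41248511
0.09817477	8.0146085
0.14726216	7.62637018
0.19634954	7.24777014
0.24543693	6.87880839
0.29452431	6.51948493
0.3436117	6.16979975
0.39269908	5.82975285
0.44178647	5.49934424
0.49087385	5.17857392
0.53996124	4.86744188
0.58904862	4.56594813
0.63813601	4.27409266
0.68722339	3.99187548
0.73631078	3.71929659
0.78539816	3.45635598
0.83448555	3.20305365
0.88357293	2.95938961
0.93266032	2.72536386
0.9817477	2.50097639
1.03083509	2.28622721
1.07992247	2.08111632
1.12900986	1.8856437
1.17809725	1.69980938
1.22718463	1.52361334
1.27627202	1.35705558
1.3253594	1.20013612
1.37444679	1.05285493
1.42353417	0.91521204
1.47262156	0.78720742
1.52170894	0.6688411
1.57079633	0.56011306
1.61988371	0.4610233
1.6689711	0.37157183
1.71805848	0.29175865
1.76714587	0.22158375
1.81623325	0.16104713
1.86532064	0.11014881
1.91440802	0.06888876
1.96349541	0.03726701
2.01258279	0.01528354
2.06167018	0.00293835
2.11075756	0.00023145
2.15984495	0.00716284
2.20893233	0.02373251
2.25801972	0.04994046
2.3071071	0.08578671
2.35619449	0.13127123
2.40528188	0.18639405
2.45436926	0.25115515
2.50345665	0.32555453
2.55254403	0.4095922
2.60163142	0.50326816
2.6507188	0.6065824
2.69980619	0.71953492
2.74889357	0.84212574
2.79798096	0.97435483
2.84706834	1.11622222
2.89615573	1.26772788
2.94524311	1.42887184
2.9943305	1.59965408
3.04341788	1.7800746
3.09250527	1.97013342
3.14159265	2.16983051
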