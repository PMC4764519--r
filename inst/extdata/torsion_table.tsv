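angle	energy
-3.14159265	0
-3.05432619	0.0121249
-2.96705973	0.0477885
-2.87979327	0.10490505
-2.7925268	0.18015369
-2.70526034	0.26920039
-2.61799388	0.3669873
-2.53072742	0.46806969
-2.44346095	0.56697778
-2.35619449	0.65857864
-2.26892803	0.73841382
-2.18166156	0.80298953
-2.0943951	0.85
-2.00712864	0.87846862
-1.91986218	0.88879755
-1.83259571	0.88272251
-1.74532925	0.86317591
-1.65806279	0.83406784
-1.57079633	0.8
-1.48352986	0.76593216
-1.3962634	0.73682409
-1.30899694	0.71727749
-1.22173048	0.71120245
-1.13446401	0.72153138
-1.04719755	0.75
-0.95993109	0.79701047
-0.87266463	0.86158618
-0.78539816	0.94142136
-0.6981317	1.03302222
-0.61086524	1.13193031
-0.52359878	1.2330127
-0.43633231	1.33079961
-0.34906585	1.41984631
-0.26179939	1.49509495
-0.17453293	1.5522115
-0.08726646	1.5878751
0	1.6
0.08726646	1.5878751
0.17453293	1.5522115
0.26179939	1.49509495
0.34906585	1.41984631
0.43633231	1.33079961
0.52359878	1.2330127
0.61086524	1.13193031
0.6981317	1.03302222
0.78539816	0.94142136
0.87266463	0.86158618
0.95993109	0.79701047
1.04719755	0.75
1.13446401	0.72153138
1.22173048	0.71120245
1.30899694	0.71727749
1.3962634	0.73682409
1.48352986	0.76593216
1.57079633	0.8
1.65806279	0.83406784
1.74532925	0.86317591
1.83259571	0.88272251
1.91986218	0.88879755
2.00712864	0.87846862
2.0943951	0.85
2.18166156	0.80298953
2.26892803	0.73841382
2.35619449	0.65857864
2.44346095	0.56697778
2.53072742	0.46806969
2.61799388	0.3669873
2.70526034	0.26920039
2.7925268	0.18015369
2.87979327	0.10490505
2.96705973	0.0477885
3.05432619	0.0121249
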