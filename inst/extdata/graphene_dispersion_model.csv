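wavelength_nm,n,k
400,1.6443,1.3053
410,1.6601,1.3252
420,1.6758,1.3448
430,1.6914,1.3641
440,1.7068,1.3832
450,1.7221,1.4021
460,1.7373,1.4207
470,1.7524,1.4391
480,1.7674,1.4573
490,1.7822,1.4752
500,1.797,1.493
510,1.8116,1.5106
520,1.8261,1.5279
530,1.8405,1.5451
540,1.8548,1.5621
550,1.869,1.579
560,1.8831,1.5957
570,1.8971,1.6122
580,1.911,1.6285
590,1.9248,1.6447
600,1.9386,1.6607
610,1.9522,1.6766
620,1.9657,1.6924
630,1.9792,1.708
640,1.9926,1.7234
650,2.0058,1.7388
660,2.019,1.754
670,2.0321,1.7691
680,2.0452,1.784
690,2.0581,1.7989
700,2.071,1.8136
710,2.0838,1.8282
720,2.0966,1.8427
730,2.1092,1.8571
740,2.1218,1.8714
750,2.1343,1.8855
760,2.1467,1.8996
770,2.1591,1.9136
780,2.1714,1.9274
790,2.1836,1.9412
800,2.1958,1.9549
810,2.2079,1.9685
820,2.22,1.982
830,2.2319,1.9954
840,2.2438,2.0087
850,2.2557,2.0219
860,2.2675,2.0351
870,2.2792,2.0481
880,2.2909,2.0611
890,2.3025,2.074
900,2.3141,2.0869
910,2.3256,2.0996
920,2.337,2.1123
930,2.3484,2.1249
940,2.3598,2.1374
950,2.3711,2.1499
960,2.3823,2.1622
970,2.3935,2.1746
980,2.4046,2.1868
990,2.4157,2.199
1000,2.4267,2.2111
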