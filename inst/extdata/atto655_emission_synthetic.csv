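wavelength_nm,weight
650,0.2663
652,0.3466
654,0.4313
656,0.5171
658,0.6008
660,0.6798
662,0.752
664,0.816
666,0.8706
668,0.9155
670,0.9506
672,0.976
674,0.9922
676,1
678,1
680,0.9931
682,0.9803
684,0.9622
686,0.9398
688,0.9139
690,0.8851
692,0.854
694,0.8214
696,0.7877
698,0.7533
700,0.7186
702,0.6841
704,0.6498
706,0.6162
708,0.5833
710,0.5513
712,0.5204
714,0.4905
716,0.4619
718,0.4344
720,0.4082
722,0.3833
724,0.3596
726,0.3371
728,0.3158
730,0.2957
732,0.2767
734,0.2588
736,0.242
738,0.2261
740,0.2113
742,0.1973
744,0.1842
746,0.172
748,0.1605
750,0.1498
752,0.1397
754,0.1303
756,0.1216
758,0.1134
760,0.1058
762,0.0986
764,0.092
766,0.0858
768,0.08
770,0.0746
772,0.0695
774,0.0649
776,0.0605
778,0.0564
780,0.0526
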