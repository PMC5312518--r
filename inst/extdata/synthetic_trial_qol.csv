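patient_id,time,score
P01,0.000,0.809
P01,1.673,0.693
P01,4.584,0.719
P01,5.776,0.521
P02,0.000,0.845
P02,0.798,0.758
P02,1.814,0.707
P02,2.234,0.633
P03,0.000,0.856
P03,0.550,0.742
P03,1.316,0.635
P03,3.236,0.553
P04,0.000,0.779
P04,0.960,0.736
P04,2.188,0.693
P04,2.236,0.480
P05,0.000,0.833
P05,1.992,0.714
P05,3.336,0.680
P05,3.772,0.640
P06,0.000,0.819
P06,0.721,0.799
P06,1.776,0.645
P06,2.229,0.538
P07,0.000,0.754
P07,0.341,0.740
P07,1.361,0.672
P07,1.622,0.555
P08,0.000,0.884
P08,0.260,0.769
P08,0.310,0.649
P09,0.000,0.889
P09,1.602,0.882
P09,3.131,0.669
P09,3.148,0.642
P10,0.000,0.811
P10,0.210,0.635
P10,0.891,0.618
P10,1.947,0.568
P11,0.000,0.811
P11,0.630,0.649
P11,0.651,0.740
P11,0.861,0.564
P12,0.000,0.765
P12,0.768,0.697
P12,1.922,0.677
P12,3.813,0.543
P13,0.000,0.849
P13,0.230,0.781
P13,0.308,0.634
P13,1.432,0.526
P14,0.000,0.851
P14,0.325,0.819
P14,0.636,0.593
P14,2.330,0.632
P15,0.000,0.775
P15,0.417,0.797
P15,0.796,0.611
P15,1.652,0.589
P16,0.000,0.881
P16,0.996,0.656
P16,1.479,0.676
P16,2.189,0.563
P17,0.000,0.773
P17,0.390,0.767
P17,1.229,0.723
P17,1.286,0.498
P18,0.000,0.876
P18,1.308,0.673
P18,2.311,0.723
P18,2.803,0.592
P19,0.000,0.824
P19,0.396,0.803
P19,5.458,0.668
P19,5.804,0.600
P20,0.000,0.893
P20,0.294,0.778
P20,0.898,0.694
P20,1.611,0.561
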