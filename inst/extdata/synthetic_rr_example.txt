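# synthetic 330 s R-R interval record (ms, one per line), LF+HF modulated
839.820
866.646
859.775
837.315
846.545
861.928
853.279
815.569
776.433
780.989
801.804
841.347
838.613
826.043
808.190
866.600
859.961
841.243
793.604
791.917
836.548
823.499
810.116
794.330
827.974
843.031
862.587
849.903
813.268
844.871
836.773
823.028
788.386
800.283
807.184
838.792
836.303
817.995
829.215
867.917
863.533
843.625
817.480
829.790
812.128
823.885
805.676
801.479
825.147
874.198
859.345
837.654
827.034
834.055
845.254
815.776
805.365
784.763
818.631
833.222
850.100
831.768
838.453
863.718
889.439
843.796
793.302
816.506
828.077
802.258
815.574
782.164
818.023
852.278
867.807
844.955
847.780
849.711
841.988
832.895
785.563
796.439
815.236
814.883
836.594
834.860
828.875
856.198
871.282
858.595
803.810
803.160
814.381
831.944
812.230
773.195
798.986
834.718
865.836
863.548
856.311
845.057
862.907
837.938
788.864
789.806
800.992
841.404
830.381
813.269
815.064
865.408
866.917
855.326
813.847
789.341
838.141
831.299
807.057
803.117
804.782
839.861
852.819
852.372
828.049
838.738
841.115
831.035
802.273
791.578
788.385
826.851
830.553
827.186
842.097
840.903
860.846
866.984
828.839
804.537
822.348
814.041
805.862
812.778
811.228
844.200
881.934
858.426
845.207
847.659
839.840
843.730
834.522
799.043
789.720
795.375
840.453
824.371
817.464
849.694
889.460
862.778
826.965
823.277
812.654
820.190
815.802
778.253
813.429
856.731
860.431
867.622
832.313
838.405
854.446
857.154
824.716
788.733
802.738
819.653
844.130
830.250
831.136
840.158
868.192
871.306
837.828
804.099
809.198
831.277
809.112
785.432
806.165
844.079
876.325
864.794
850.336
841.076
873.336
827.170
813.135
792.191
787.031
824.111
847.380
818.130
816.411
846.001
879.836
869.481
822.834
813.663
809.296
798.943
823.516
800.930
806.226
836.120
856.314
871.548
832.585
850.043
850.579
847.109
817.191
791.082
791.713
823.982
834.363
835.820
836.797
849.382
867.871
863.248
832.316
809.474
813.136
820.939
818.768
788.507
800.167
838.941
874.644
872.896
830.792
853.606
843.035
851.321
807.481
791.157
808.647
819.976
846.984
827.262
825.857
825.350
870.075
867.056
840.815
797.716
810.246
822.197
824.787
791.270
771.446
830.063
853.965
870.868
847.953
843.178
855.784
848.604
809.752
783.733
794.862
814.243
829.402
816.374
813.489
834.393
871.074
874.211
855.520
813.667
816.845
820.608
814.006
802.208
806.109
845.679
849.716
872.558
860.753
829.502
849.015
858.378
839.079
780.497
775.750
813.217
841.970
826.599
819.730
845.370
879.815
876.450
841.109
819.018
812.308
837.468
825.761
788.027
778.970
810.151
883.657
860.713
844.967
833.889
854.982
845.406
818.045
797.285
791.363
803.079
860.437
831.930
812.798
840.170
842.759
869.447
847.276
807.671
822.594
818.278
835.008
788.700
807.880
794.954
851.306
870.325
841.725
817.687
845.397
852.844
841.301
813.996
775.041
810.734
820.517
848.257
819.711
838.159
865.602
866.219
830.314
812.019
815.452
829.338
836.811
795.585
791.388
816.419
840.025
859.642
855.815
828.817
842.155
853.608
843.462
795.110
803.482
798.793
825.713
834.647
825.268
826.696
852.486
869.295
878.831
810.858
809.474
817.404
828.502
809.524
809.238
812.324
828.479
874.184
851.848
846.759
839.658
859.673
848.198
792.480
800.220
806.845
824.643
834.869
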