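wavelength_nm,eps_hbo2,eps_hhb,eps_oxcco
780,0.000697802,0.0013025,0.00104263
781,0.000702235,0.00129044,0.00107405
782,0.000706658,0.00127826,0.00110698
783,0.000711072,0.00126601,0.00114146
784,0.000715476,0.00125371,0.00117748
785,0.000719871,0.00124138,0.00121504
786,0.000724254,0.00122906,0.00125414
787,0.000728626,0.00121678,0.00129477
788,0.000732986,0.00120455,0.00133689
789,0.000737334,0.00119241,0.00138049
790,0.00074167,0.00118038,0.00142552
791,0.000745992,0.00116847,0.00147194
792,0.0007503,0.00115672,0.0015197
793,0.000754594,0.00114513,0.00156873
794,0.000758874,0.00113372,0.00161896
795,0.000763138,0.00112251,0.00167031
796,0.000767385,0.00111151,0.0017227
797,0.000771617,0.00110073,0.00177602
798,0.000775831,0.00109018,0.00183017
799,0.000780027,0.00107987,0.00188503
800,0.000784205,0.0010698,0.00194047
801,0.000788365,0.00105999,0.00199638
802,0.000792505,0.00105042,0.0020526
803,0.000796624,0.00104112,0.00210899
804,0.000800723,0.00103206,0.00216541
805,0.000804801,0.00102326,0.00222168
806,0.000808857,0.00101471,0.00227766
807,0.000812891,0.00100642,0.00233316
808,0.000816902,0.000998363,0.00238802
809,0.000820889,0.00099055,0.00244207
810,0.000824852,0.000982973,0.00249512
811,0.000828791,0.000975624,0.002547
812,0.000832704,0.000968497,0.00259754
813,0.000836592,0.000961585,0.00264654
814,0.000840454,0.000954879,0.00269385
815,0.000844289,0.000948373,0.00273929
816,0.000848097,0.000942057,0.00278269
817,0.000851878,0.000935922,0.00282388
818,0.000855631,0.000929962,0.00286272
819,0.000859355,0.000924166,0.00289905
820,0.000863052,0.000918526,0.00293273
821,0.000866719,0.000913033,0.00296363
822,0.000870358,0.00090768,0.00299162
823,0.000873967,0.000902457,0.00301659
824,0.000877547,0.000897357,0.00303844
825,0.000881097,0.000892372,0.00305709
826,0.000884617,0.000887494,0.00307245
827,0.000888108,0.000882716,0.00308447
828,0.000891569,0.00087803,0.00309308
829,0.000895,0.000873431,0.00309827
830,0.000898402,0.00086891,0.0031
831,0.000901774,0.000864463,0.00309827
832,0.000905117,0.000860084,0.00309308
833,0.000908431,0.000855766,0.00308447
834,0.000911716,0.000851506,0.00307245
835,0.000914974,0.000847297,0.00305709
836,0.000918203,0.000843136,0.00303844
837,0.000921405,0.000839017,0.00301659
838,0.000924581,0.000834939,0.00299162
839,0.00092773,0.000830895,0.00296363
840,0.000930854,0.000826884,0.00293273
841,0.000933954,0.000822902,0.00289905
842,0.00093703,0.000818946,0.00286272
843,0.000940083,0.000815014,0.00282388
844,0.000943115,0.000811103,0.00278269
845,0.000946126,0.000807211,0.00273929
846,0.000949117,0.000803336,0.00269385
847,0.00095209,0.000799476,0.00264654
848,0.000955046,0.000795629,0.00259754
849,0.000957986,0.000791794,0.002547
850,0.000960911,0.00078797,0.00249512
851,0.000963824,0.000784156,0.00244207
852,0.000966725,0.000780349,0.00238802
853,0.000969616,0.00077655,0.00233316
854,0.000972499,0.000772758,0.00227766
855,0.000975376,0.000768971,0.00222168
856,0.000978248,0.000765189,0.00216541
857,0.000981117,0.000761412,0.00210899
858,0.000983985,0.000757638,0.0020526
859,0.000986854,0.000753867,0.00199638
860,0.000989725,0.0007501,0.00194047
861,0.000992601,0.000746335,0.00188503
862,0.000995484,0.000742572,0.00183017
863,0.000998376,0.000738811,0.00177602
864,0.00100128,0.000735051,0.0017227
865,0.00100419,0.000731293,0.00167031
866,0.00100713,0.000727536,0.00161896
867,0.00101007,0.000723781,0.00156873
868,0.00101304,0.000720026,0.0015197
869,0.00101603,0.000716271,0.00147194
870,0.00101904,0.000712518,0.00142552
871,0.00102208,0.000708765,0.00138049
872,0.00102515,0.000705012,0.00133689
873,0.00102825,0.00070126,0.00129477
874,0.00103138,0.000697509,0.00125414
875,0.00103454,0.000693757,0.00121504
876,0.00103774,0.000690006,0.00117748
877,0.00104098,0.000686255,0.00114146
878,0.00104426,0.000682504,0.00110698
879,0.00104759,0.000678753,0.00107405
880,0.00105095,0.000675003,0.00104263
881,0.00105437,0.000671252,0.00101273
882,0.00105783,0.000667502,0.000984318
883,0.00106134,0.000663752,0.000957364
884,0.0010649,0.000660001,0.000931841
885,0.00106852,0.000656251,0.000907714
886,0.00107219,0.000652501,0.000884946
887,0.00107592,0.000648751,0.000863498
888,0.00107971,0.000645001,0.000843327
889,0.00108355,0.00064125,0.000824389
890,0.00108745,0.0006375,0.000806639
891,0.00109142,0.00063375,0.000790029
892,0.00109545,0.00063,0.000774512
893,0.00109954,0.00062625,0.000760041
894,0.00110369,0.0006225,0.000746567
895,0.00110791,0.00061875,0.000734041
896,0.0011122,0.000615,0.000722416
897,0.00111655,0.00061125,0.000711645
898,0.00112097,0.0006075,0.00070168
899,0.00112545,0.00060375,0.000692477
900,0.00113,6e-04,0.00068399
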