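sample_id,sepal_length,sepal_width,petal_length,petal_width
iris_001,5.1,3.5,1.4,0.2
iris_002,4.9,3,1.4,0.2
iris_003,4.7,3.2,1.3,0.2
iris_004,4.6,3.1,1.5,0.2
iris_005,5,3.6,1.4,0.2
iris_006,5.4,3.9,1.7,0.4
iris_007,4.6,3.4,1.4,0.3
iris_008,5,3.4,1.5,0.2
iris_009,4.4,2.9,1.4,0.2
iris_010,4.9,3.1,1.5,0.1
iris_011,5.4,3.7,1.5,0.2
iris_012,4.8,3.4,1.6,0.2
iris_013,4.8,3,1.4,0.1
iris_014,4.3,3,1.1,0.1
iris_015,5.8,4,1.2,0.2
iris_016,5.7,4.4,1.5,0.4
iris_017,5.4,3.9,1.3,0.4
iris_018,5.1,3.5,1.4,0.3
iris_019,5.7,3.8,1.7,0.3
iris_020,5.1,3.8,1.5,0.3
iris_021,5.4,3.4,1.7,0.2
iris_022,5.1,3.7,1.5,0.4
iris_023,4.6,3.6,1,0.2
iris_024,5.1,3.3,1.7,0.5
iris_025,4.8,3.4,1.9,0.2
iris_026,5,3,1.6,0.2
iris_027,5,3.4,1.6,0.4
iris_028,5.2,3.5,1.5,0.2
iris_029,5.2,3.4,1.4,0.2
iris_030,4.7,3.2,1.6,0.2
iris_031,4.8,3.1,1.6,0.2
iris_032,5.4,3.4,1.5,0.4
iris_033,5.2,4.1,1.5,0.1
iris_034,5.5,4.2,1.4,0.2
iris_035,4.9,3.1,1.5,0.2
iris_036,5,3.2,1.2,0.2
iris_037,5.5,3.5,1.3,0.2
iris_038,4.9,3.6,1.4,0.1
iris_039,4.4,3,1.3,0.2
iris_040,5.1,3.4,1.5,0.2
iris_041,5,3.5,1.3,0.3
iris_042,4.5,2.3,1.3,0.3
iris_043,4.4,3.2,1.3,0.2
iris_044,5,3.5,1.6,0.6
iris_045,5.1,3.8,1.9,0.4
iris_046,4.8,3,1.4,0.3
iris_047,5.1,3.8,1.6,0.2
iris_048,4.6,3.2,1.4,0.2
iris_049,5.3,3.7,1.5,0.2
iris_050,5,3.3,1.4,0.2
iris_051,7,3.2,4.7,1.4
iris_052,6.4,3.2,4.5,1.5
iris_053,6.9,3.1,4.9,1.5
iris_054,5.5,2.3,4,1.3
iris_055,6.5,2.8,4.6,1.5
iris_056,5.7,2.8,4.5,1.3
iris_057,6.3,3.3,4.7,1.6
iris_058,4.9,2.4,3.3,1
iris_059,6.6,2.9,4.6,1.3
iris_060,5.2,2.7,3.9,1.4
iris_061,5,2,3.5,1
iris_062,5.9,3,4.2,1.5
iris_063,6,2.2,4,1
iris_064,6.1,2.9,4.7,1.4
iris_065,5.6,2.9,3.6,1.3
iris_066,6.7,3.1,4.4,1.4
iris_067,5.6,3,4.5,1.5
iris_068,5.8,2.7,4.1,1
iris_069,6.2,2.2,4.5,1.5
iris_070,5.6,2.5,3.9,1.1
iris_071,5.9,3.2,4.8,1.8
iris_072,6.1,2.8,4,1.3
iris_073,6.3,2.5,4.9,1.5
iris_074,6.1,2.8,4.7,1.2
iris_075,6.4,2.9,4.3,1.3
iris_076,6.6,3,4.4,1.4
iris_077,6.8,2.8,4.8,1.4
iris_078,6.7,3,5,1.7
iris_079,6,2.9,4.5,1.5
iris_080,5.7,2.6,3.5,1
iris_081,5.5,2.4,3.8,1.1
iris_082,5.5,2.4,3.7,1
iris_083,5.8,2.7,3.9,1.2
iris_084,6,2.7,5.1,1.6
iris_085,5.4,3,4.5,1.5
iris_086,6,3.4,4.5,1.6
iris_087,6.7,3.1,4.7,1.5
iris_088,6.3,2.3,4.4,1.3
iris_089,5.6,3,4.1,1.3
iris_090,5.5,2.5,4,1.3
iris_091,5.5,2.6,4.4,1.2
iris_092,6.1,3,4.6,1.4
iris_093,5.8,2.6,4,1.2
iris_094,5,2.3,3.3,1
iris_095,5.6,2.7,4.2,1.3
iris_096,5.7,3,4.2,1.2
iris_097,5.7,2.9,4.2,1.3
iris_098,6.2,2.9,4.3,1.3
iris_099,5.1,2.5,3,1.1
iris_100,5.7,2.8,4.1,1.3
iris_101,6.3,3.3,6,2.5
iris_102,5.8,2.7,5.1,1.9
iris_103,7.1,3,5.9,2.1
iris_104,6.3,2.9,5.6,1.8
iris_105,6.5,3,5.8,2.2
iris_106,7.6,3,6.6,2.1
iris_107,4.9,2.5,4.5,1.7
iris_108,7.3,2.9,6.3,1.8
iris_109,6.7,2.5,5.8,1.8
iris_110,7.2,3.6,6.1,2.5
iris_111,6.5,3.2,5.1,2
iris_112,6.4,2.7,5.3,1.9
iris_113,6.8,3,5.5,2.1
iris_114,5.7,2.5,5,2
iris_115,5.8,2.8,5.1,2.4
iris_116,6.4,3.2,5.3,2.3
iris_117,6.5,3,5.5,1.8
iris_118,7.7,3.8,6.7,2.2
iris_119,7.7,2.6,6.9,2.3
iris_120,6,2.2,5,1.5
iris_121,6.9,3.2,5.7,2.3
iris_122,5.6,2.8,4.9,2
iris_123,7.7,2.8,6.7,2
iris_124,6.3,2.7,4.9,1.8
iris_125,6.7,3.3,5.7,2.1
iris_126,7.2,3.2,6,1.8
iris_127,6.2,2.8,4.8,1.8
iris_128,6.1,3,4.9,1.8
iris_129,6.4,2.8,5.6,2.1
iris_130,7.2,3,5.8,1.6
iris_131,7.4,2.8,6.1,1.9
iris_132,7.9,3.8,6.4,2
iris_133,6.4,2.8,5.6,2.2
iris_134,6.3,2.8,5.1,1.5
iris_135,6.1,2.6,5.6,1.4
iris_136,7.7,3,6.1,2.3
iris_137,6.3,3.4,5.6,2.4
iris_138,6.4,3.1,5.5,1.8
iris_139,6,3,4.8,1.8
iris_140,6.9,3.1,5.4,2.1
iris_141,6.7,3.1,5.6,2.4
iris_142,6.9,3.1,5.1,2.3
iris_143,5.8,2.7,5.1,1.9
iris_144,6.8,3.2,5.9,2.3
iris_145,6.7,3.3,5.7,2.5
iris_146,6.7,3,5.2,2.3
iris_147,6.3,2.5,5,1.9
iris_148,6.5,3,5.2,2
iris_149,6.2,3.4,5.4,2.3
iris_150,5.9,3,5.1,1.8
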