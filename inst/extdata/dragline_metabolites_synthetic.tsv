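name	category	intensity
xanthurenic acid	organic acids	3032943.7
metabolite_001	organic acids	2372337
metabolite_002	organic acids	2029333.5
metabolite_003	organic acids	1240572.3
metabolite_004	organic acids	656887.6
metabolite_005	organic acids	651498
metabolite_006	organic acids	563103.8
metabolite_007	organic acids	525865.3
metabolite_008	organic acids	484614.7
metabolite_009	organic acids	431810.1
metabolite_010	organic acids	371840.4
metabolite_011	organic acids	370452.4
metabolite_012	organic acids	312721
metabolite_013	organic acids	310895.2
metabolite_014	organic acids	289993.8
metabolite_015	organic acids	284350.1
metabolite_016	organic acids	279094.7
metabolite_017	organic acids	248395.7
metabolite_018	organic acids	243935.2
metabolite_019	organic acids	232577.4
metabolite_020	organic acids	225032.3
metabolite_021	organic acids	219503.1
metabolite_022	organic acids	208528.6
metabolite_023	organic acids	206679.3
metabolite_024	organic acids	184432.5
metabolite_025	organic acids	145253.4
metabolite_026	organic acids	143851.9
metabolite_027	organic acids	131069.8
metabolite_028	organic acids	130627.1
metabolite_029	organic acids	130033
metabolite_030	organic acids	128519.7
metabolite_031	organic acids	128042.4
metabolite_032	organic acids	118772.8
metabolite_033	organic acids	118595.1
metabolite_034	organoheterocyclic compounds	106909.8
metabolite_035	organoheterocyclic compounds	99588.6
metabolite_036	organoheterocyclic compounds	93686.8
metabolite_037	organoheterocyclic compounds	91338.4
metabolite_038	organoheterocyclic compounds	87482.4
metabolite_039	organoheterocyclic compounds	85583.6
metabolite_040	organoheterocyclic compounds	84300.9
metabolite_041	organoheterocyclic compounds	76867.3
metabolite_042	organoheterocyclic compounds	72661.2
metabolite_043	organoheterocyclic compounds	71058
metabolite_044	organoheterocyclic compounds	71036.2
metabolite_045	organoheterocyclic compounds	71013.3
metabolite_046	organoheterocyclic compounds	65405.4
metabolite_047	organoheterocyclic compounds	65202.5
metabolite_048	organoheterocyclic compounds	64694
metabolite_049	organoheterocyclic compounds	61798.3
metabolite_050	organoheterocyclic compounds	61463
metabolite_051	organoheterocyclic compounds	60651.7
metabolite_052	organoheterocyclic compounds	59842.3
metabolite_053	organoheterocyclic compounds	58617.2
metabolite_054	organoheterocyclic compounds	58067.1
metabolite_055	organoheterocyclic compounds	54554.3
metabolite_056	lipids	54496.9
metabolite_057	lipids	53924
metabolite_058	lipids	52975.6
metabolite_059	lipids	51608.8
metabolite_060	lipids	49174.5
metabolite_061	lipids	47956.9
metabolite_062	lipids	46972.8
metabolite_063	lipids	44583.3
metabolite_064	lipids	42820.4
metabolite_065	lipids	42566.4
metabolite_066	lipids	41398.2
metabolite_067	lipids	41080.8
metabolite_068	lipids	40528.3
metabolite_069	lipids	38607.5
metabolite_070	lipids	36942.6
metabolite_071	lipids	35856.4
metabolite_072	benzenoids	34771
metabolite_073	benzenoids	34190.6
metabolite_074	benzenoids	30284.3
metabolite_075	benzenoids	30126.1
metabolite_076	benzenoids	27258.4
metabolite_077	benzenoids	27180.3
metabolite_078	benzenoids	25497.6
metabolite_079	benzenoids	24843
metabolite_080	benzenoids	23442.2
metabolite_081	benzenoids	23229.7
metabolite_082	benzenoids	22942.9
metabolite_083	benzenoids	22576.3
metabolite_084	benzenoids	22344.1
metabolite_085	organic nitrogen compounds	22292.9
metabolite_086	organic nitrogen compounds	21338.8
metabolite_087	organic nitrogen compounds	20686.8
metabolite_088	organic nitrogen compounds	20536.2
metabolite_089	organic nitrogen compounds	20101.6
metabolite_090	organic oxygen compounds	19350.1
metabolite_091	organic oxygen compounds	18839.2
metabolite_092	organic oxygen compounds	18801.1
metabolite_093	organic oxygen compounds	18118.3
metabolite_094	organic oxygen compounds	17634.4
metabolite_095	organic oxygen compounds	17325.2
metabolite_096	organic oxygen compounds	17285
metabolite_097	organic oxygen compounds	17208.1
metabolite_098	nucleosides	16693.8
metabolite_099	nucleosides	16102.2
metabolite_100	nucleosides	15182.4
metabolite_101	nucleosides	15135.5
metabolite_102	nucleosides	14687.7
metabolite_103	organooxygen compounds	14155.9
metabolite_104	organooxygen compounds	14101.8
metabolite_105	organooxygen compounds	13905.1
metabolite_106	phenylpropanoids and polyketides	13282.1
metabolite_107	phenylpropanoids and polyketides	13211.9
metabolite_108	alkaloids	12533.4
metabolite_109		12418.4
metabolite_110		12272.1
metabolite_111		11529.5
metabolite_112		11072.8
metabolite_113		10987.2
metabolite_114		10974.1
metabolite_115		10954.2
metabolite_116		10881.5
metabolite_117		9555.2
metabolite_118		9105.8
metabolite_119		9088.7
metabolite_120		7827.2
metabolite_121		7737.8
metabolite_122		7433
metabolite_123		7101.5
metabolite_124		6754.3
metabolite_125		6739.2
metabolite_126		6605.4
metabolite_127		6591.6
metabolite_128		6559.3
metabolite_129		6530.6
metabolite_130		6485
metabolite_131		6124.3
metabolite_132		5934.7
metabolite_133		5624.9
metabolite_134		5555
metabolite_135		4787.7
metabolite_136		4762.8
metabolite_137		4756.2
metabolite_138		4528.1
metabolite_139		4285.5
metabolite_140		4201.2
metabolite_141		4031.8
metabolite_142		3997.1
metabolite_143		3866.6
metabolite_144		3844.9
metabolite_145		3836.1
metabolite_146		3586.1
metabolite_147		3400.6
metabolite_148		3373.5
metabolite_149		3080.4
metabolite_150		3037.1
metabolite_151		3036.8
metabolite_152		2956.5
metabolite_153		2941.9
metabolite_154		2819.4
metabolite_155		2604.3
metabolite_156		2564.4
metabolite_157		2527.9
metabolite_158		2492.9
metabolite_159		2419.8
metabolite_160		2252.3
metabolite_161		2208.6
metabolite_162		2017.5
metabolite_163		1643
metabolite_164		1608.9
metabolite_165		1443.3
metabolite_166		1290.3
metabolite_167		1083.5
metabolite_168		1060.9
metabolite_169		1015.8
metabolite_170		1015.3
metabolite_171		980.2
metabolite_172		939.2
metabolite_173		905.2
metabolite_174		834.6
metabolite_175		445.7
metabolite_176		350.9
metabolite_177		277.7
metabolite_178		240.7
metabolite_179		221.9
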