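scientific_name	group	presence_abundance	genbank_accessions
Acidaminococcus fermentans	Bac/Firmicute	(100;0.04)	CP001859
Clostridium saccharolyticum	Bac/Firmicute	(100;0.24)	CP002109,FP929037
Odoribacter splanchnicus	Bac/CFB_bac	(100;1.12)	CP002544
Acidaminococcus intestine	Bac/Firmicute	(100;0.09)	CP003058
Coprococcus catus	Bac/Firmicute	(100;0.37)	FP929038
Ornithobacterium rhinotracheale	Bac/CFB_bac	(100;0.11)	CP006828
Acidovorax sp KKS102	Bac/Beta-proteo	(100;0.01)	CP003872
Coprococcus sp ART55/1	Bac/Firmicute	(100;0.68)	FP929039
Oscillibacter valericigenes	Bac/Firmicute	(100;0.05)	AP012044
Adlercreutzia equolifaciens	Bac/ActnBac	(100;0.07)	AP013105
Cutibacterium acnes	Bac/ActnBac	(100;0.004)	CP003084
Paenibacillus sabinae	Bac/Firmicute	(100;0.01)	CP004078
Akkermansia muciniphila	Other Bacteria	(91.84;0.70)	CP001071
Eggerthella lenta	Bac/ActnBac	(100;0.04)	CP001726
Paeniclostridium sordellii	Bac/Firmicute	(100;0.02)	LN679998,LN681234
Alistipes finegoldii	Alistipes finegoldii	(100;1.27)	CP003274
Eggerthella sp. YY7918	Bac/ActnBac	(100;0.01)	AP012211
Parabacteroides distasonis	Bac/CFB_bac	(100;2.30)	CP000140
Alistipes shahii	Bac/CFB_bac	(100;1.75)	FP929032
Enterococcus faecium	Bac/Firmicute	(100;0.04)	CP003351,CP006620,CP006030
Parvimonas micra	Bac/Firmicute	(100;0.01)	CP009761
Anaerococcus prevotii	Bac/Firmicute	(100;0.003)	CP001708
Enterococcus hirae	Bac/Firmicute	(96.94;0.004)	CP003504
Porphyromonas asaccharolytica	Bac/CFB_bac	(98.98;0.01)	CP002689
Anaerostipes hadrus	Bac/Firmicute	(100;0.55)	FP929061
Escherichia coli	Bac/Gamma-proteo	(100;1.87)	CP009859,CP010816,CP000948,CP001637,CP000970,CP000243,CP009166,CP002291,CP003297,CP007394,AP009378,AE014075,CP010371,CP002729,CP007799,CP001396,CP009789,CP004009,CP007390,FN649414,CP009167,HG941718
Porphyromonas gingivalis	Bac/CFB_bac	(100;0.01)	AP009380
Bacillus methanolicus	Bac/Firmicute	(100;0.01)	CP007739
Escherichia coli O104:H4	Bac/Gamma-proteo	(96.94;0.04)	CP004009
Prevotella dentalis	Bac/CFB_bac	(100;0.08)	CP003368,CP003369
Bacteroides cellulosilyticus	Bac/CFB_bac	(100;3.38)	CP012801
Escherichia coli O83:H1	Bac/Gamma-proteo	(95.92;0.06)	CU651637
Prevotella denticola	Bac/CFB_bac	(98.98;0.04)	CP002589
Bacteroides dorei	Bac/CFB_bac	(100;17.44)	CP007619,CP009057
Ethanoligenens harbinense	Bac/Firmicute	(100;0.01)	CP002400
Prevotella intermedia	Bac/CFB_bac	(100;0.07)	AP014597,CP003502,CP003503,AP014598
Bacteroides fragilis	Bac/CFB_bac	(100;3.47)	FQ312004,CR626927,AP006841,AP006842,CR626928
Eubacterium eligens	Bac/Firmicute	(100;0.65)	CP001104,CP001105,CP001106
Prevotella melaninogenica	Bac/CFB_bac	(100;0.24)	CP002122,CP002123
Bacteroides helcogenes	Bac/CFB_bac	(100;0.50)	CP002352
Eubacterium limosum	Bac/Firmicute	(100;0.03)	CP002273
Prevotella ruminicola	Bac/CFB_bac	(100;0.06)	CP002006
Bacteroides ovatus	Bac/CFB_bac	(100;7.72)	CP012938
[Eubacterium] rectale	Bac/Firmicute	(100;6.21)	FP929042,FP929043,CP001107
Prevotella sp oral taxon 299	Bac/CFB_bac	(100;0.06)	CP003666
Bacteroides salanitronis	Bac/CFB_bac	(100;0.48)	CP002530
[Eubacterium] siraeum	Bac/Firmicute	(100;0.75)	FP929044,FP929059
Raoultella ornithinolytica	Bac/Gamma-proteo	(100;0.01)	CP004142
Bacteroides sp. CAG:98	Bac/CFB_bac	(100;8.89)	CP008741
Faecalibacterium prausnitzii	Bac/Firmicute	(100;3.52)	FP929045,FP929046
Roseburia hominis	Bac/Firmicute	(100;0.69)	CP003040
Bacteroides thetaiotaomicron	Bac/CFB_bac	(100;3.78)	AE015928,AY171301
Faecalitalea cylindroides	Bac/Firmicute	(100;0.15)	FP929041
Roseburia intestinalis	Bac/Firmicute	(100;1.15)	FP929049,FP929050
Bacteroides vulgatus	Bac/CFB_bac	(100;14.99)	CP000139
Fermentimonas caenicola	Bac/CFB_bac	(100;0.01)	LN515532
Rubinisphaera brasiliensis	Bac/Plnctmy	(70.41;0.0002)	CP002546
Bacteroides xylanisolvens	Bac/CFB_bac	(100;4.92)	FP929033
Gardnerella vaginalis	Bac/ActnBac	(91.84;0.002)	CP001849
Ruminococcus bicirculans	Bac/Firmicute	(100;2.54)	HF545616,HF545617
Barnesiella viscericola	Bac/CFB_bac	(100;0.33)	CP007034
Gordonibacter pamelaeae	Bac/ActnBac	(100;0.03)	FP929047
Ruminococcus bromii	Bac/Firmicute	(100;0.83)	FP929051
Bifidobacterium adolescentis	Bac/ActnBac	(97.96;0.46)	CP007443,CP010437,AP009256
Haemophilus parainfluenzae	Bac/Gamma-proteo	(100;0.10)	FQ312002
Ruminococcus champanellensis	Bac/Firmicute	(100;0.04)	FP929052
Bifidobacterium animalis	Bac/ActnBac	(100;0.03)	CP009045
Intestinimonas butyriciproducens	Bac/Firmicute	(100;0.24)	CP011307
Ruminococcus sp SR1/5	Bac/Firmicute	(100;0.68)	FP929053
Bifidobacterium bifidum	Bac/ActnBac	(100;0.31)	CP010412,CP001840,CP002220,CP001361
Klebsiella aerogenes	Bac/Gamma-proteo	(91.84;0.01)	FO203355,CP002824
Ruminococcus torques	Bac/Firmicute	(100;0.97)	FP929055
Bifidobacterium breve	Bac/ActnBac	(97.96;0.01)	CP006715,CP006713
Klebsiella michiganensis	Bac/Gamma-proteo	(93.88;0.002)	CP004887
Sphingobacterium faecium	Bac/CFB_bac	(95.92;0.04)	LK931720
Bifidobacterium dentium	Bac/ActnBac	(85.71;0.01)	AP012326
Klebsiella pneumoniae	Bac/Gamma-proteo	(88.78;0.01)	CP009208
Streptococcus mitis	Bac/Firmicute	(100;0.02)	FN568063
Bifidobacterium kashiwanohense	Bac/ActnBac	(100;0.13)	AP012327,CP007456
Klebsiella variicola	Bac/Gamma-proteo	(90.82;0.01)	CP001891
Streptococcus parasanguinis	Bac/Firmicute	(100;0.04)	CP002843,CP003122
Bifidobacterium longum	Bac/ActnBac	(100;0.74)	AP014658,CP002286,CP011964,CP000605,LN824140,AP010890,AP010889,AP010888,CP002010,FP929034,CP006741,CP002794,CP009072
Lachnoclostridium phytofermentans	Bac/Firmicute	(100;0.09)	CP000885
Streptococcus pasteurianus	Bac/Firmicute	(100;0.02)	AP012054
Bifidobacterium thermophilum	Bac/ActnBac	(100;0.005)	CP004346
Lactobacillus acidophilus	Bac/Firmicute	(93.88;0.003)	CP005926
Streptococcus salivarius	Bac/Firmicute	(100;0.09)	CP009913,FR873482,CP002888,FR873481
Blautia obeum	Bac/Firmicute	(100;0.51)	FP929054
Lactobacillus paracasei	Bac/Firmicute	(100;0.01)	AP012541
Streptococcus sp I-P16	Bac/Firmicute	(100;0.01)	CP006776
butyrate-producing bacterium SM4/1	Bac/Firmicute	(100;0.13)	FP929060
Lactobacillus rhamnosus	Bac/Firmicute	(92.86;0.01)	CP003094
Streptococcus suis	Bac/Firmicute	(100;0.02)	CP000837
butyrate-producing bacterium SS3/4	Bac/Firmicute	(100;0.36)	FP929062
Lactobacillus ruminis	Bac/Firmicute	(100;0.16)	CP003032
Streptococcus thermophilus	Bac/Firmicute	(100;0.05)	CP000024,CP000419,CP006819
Campylobacter coli	Bac/Delta-Epsilon-proteo	(100;0.01)	CP007180
Lactococcus lactis	Bac/Firmicute	(96.94;0.01)	CP006766
Tannerella forsythia	Bac/CFB_bac	(100;0.06)	CP003191
Campylobacter hominis	Bac/Delta-Epsilon-proteo	(97.96;0.003)	CP000776
Leuconostoc citreum	Bac/Firmicute	(93.88;0.003)	DQ489736
Treponema succinifaciens	Other Bacteria	(100;0.03)	CP002631
Candidatus Methanomassiliicoccus intestinalis	Arch/Euryar	(34.69;0.01)	CP005934
Mageeibacillus indolicus	Bac/Firmicute	(100;0.01)	CP001850
Veillonella parvula	Bac/Firmicute	(100;0.05)	CP001820
Citrobacter freundii	Bac/Gamma-proteo	(84.69;0.02)	CP007557
Megamonas sp Calf98-2	Bac/Firmicute	(100;0.02)	FP929048
Clostridioides difficile	Bac/Firmicute	(1.02;2.10)	CP003939,CP010905
Methanobrevibacter smithii	Arch/Euryar	(39.80;0.07)	CP000678
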