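index,name,domain,domain_ambiguous,prohapten_flag
1,"2,4-Dinitrochlorobenzen",snar,FALSE,
2,Methylisothiazolinone,sn2,FALSE,
3,"1,4-Phenylenediamine",michael_acceptor,FALSE,
4,Tetrachlorosalicylanilide,acyl_transfer,FALSE,
5,Dimethyl fumarate,michael_acceptor,FALSE,
6,Diphencyclopropenone,acyl_transfer,FALSE,
7,Benzisothiazolinone,sn2,FALSE,
8,Cinnamic aldehyde,michael_acceptor,FALSE,
9,Diethyl maleate,michael_acceptor,FALSE,
10,3-Dimethylaminopropylamine,schiff_base,FALSE,pro
11,Formaldehyde,schiff_base,FALSE,
12,Glutaraldehyde,schiff_base,FALSE,
13,Glyoxal,schiff_base,FALSE,
14,Lyral,schiff_base,FALSE,
15,Isoeugenol,michael_acceptor,FALSE,
16,Lauryl gallate,michael_acceptor,FALSE,
17,Methyl heptine carbonate,michael_acceptor,FALSE,
18,Methyldibromo glutaronitrile,sn2,FALSE,
19,"2-Nitro-1,4-phenylenediamine",sn2,FALSE,
20,Propyl gallate,michael_acceptor,FALSE,
21,Thioglycerol,sn2,TRUE,
22,Toluene diamine sulfate,michael_acceptor,FALSE,
23,Methyl 2-nonynoate,michael_acceptor,FALSE,
24,2-Methoxy-4-methylphenol,michael_acceptor,FALSE,pro_pre
25,Trans-2-hexenal,michael_acceptor,FALSE,
26,2-Aminophenol,michael_acceptor,FALSE,
27,Abietic acid,sn2,FALSE,
28,Benzoyl peroxide,acyl_transfer,FALSE,
29,Bisphenol A diglycidyl ether,sn2,FALSE,
30,Butyl glycidyl ether,sn2,FALSE,
31,Chlorpromazine,schiff_base,TRUE,pro_pre
32,Cinnamic alcohol,michael_acceptor,FALSE,
33,Citral,michael_acceptor,FALSE,
34,Coumarin,michael_acceptor,FALSE,
35,Ethylene diamine,schiff_base,FALSE,pro
36,Eugenol,michael_acceptor,FALSE,
37,Farnesol,michael_acceptor,FALSE,pre_pro
38,Glyceryl monothioglycolate,sn2,TRUE,
39,"1,4-Dihydroquinone",michael_acceptor,FALSE,
40,Imidazolidinyl urea,acyl_transfer,FALSE,
41,2-Mercaptobenzothiazole,acyl_transfer,FALSE,
42,"5-Methyl-2,3-hexanedione",schiff_base,FALSE,
43,Metol,michael_acceptor,FALSE,
44,Penicillin G,acyl_transfer,FALSE,
45,Phenyl benzoate,acyl_transfer,FALSE,
46,Tetramethylthiuram disulfide,acyl_transfer,FALSE,
47,3-Propylidenephthalide,michael_acceptor,FALSE,
48,Allyl phenoxyacetate,sn2,FALSE,
49,Cinnamyl nitrile,michael_acceptor,TRUE,
50,Phenylacetaldehyde,schiff_base,FALSE,
51,Dibenzyl ether,none,FALSE,
52,Benzyl alcohol,none,FALSE,
53,Amyl cinnamic aldehyde,michael_acceptor,FALSE,
54,Amylcinnamyl alcohol,michael_acceptor,TRUE,
55,Aniline,none,FALSE,pro
56,Benzocaine,none,FALSE,
57,Carvone,michael_acceptor,FALSE,
58,Ethyl acrylate,michael_acceptor,FALSE,
59,Ethyleneglycol dimethacrylate,michael_acceptor,FALSE,
60,Geraniol,schiff_base,FALSE,pro_pre
61,Hexyl salicylate,none,FALSE,
62,Hydroxycitronellal,schiff_base,FALSE,
63,Iodopropynyl butyl carbamate,acyl_transfer,FALSE,
64,Lilial,schiff_base,FALSE,
65,Linalool,none,FALSE,pre
66,Methylmethacrylate,michael_acceptor,FALSE,
67,Resorcinol,michael_acceptor,FALSE,pro
68,α-Methyl cinnamic aldehyde,michael_acceptor,FALSE,
69,"β, β 3-Trimethyl benzenepropanol",none,FALSE,
70,Benzyl cinnamate,michael_acceptor,FALSE,
71,Isocyclocitral,schiff_base,FALSE,
72,Anethole,michael_acceptor,FALSE,
73,Anisyl alcohol,none,FALSE,
74,Benzyl benzoate,none,FALSE,
75,Benzyl salicylate,none,FALSE,
76,Citronellol,none,FALSE,
77,Hexyl cinnamic aldehyde,none,FALSE,
78,Isopropyl myristate,none,FALSE,
79,Limonene,none,FALSE,pre
80,Pentachlorophenol,snar,TRUE,
81,Propyl paraben,none,FALSE,
82,Pyridine,none,FALSE,
83,Triethanolamine,none,FALSE,
84,Diethanolamine,none,FALSE,
85,Hydrocortisone,schiff_base,TRUE,
86,Isopropanol,none,FALSE,
87,Propylene glycol,none,FALSE,
88,"α-Methyl-1,3-benzodioxole-5-propionaldehyde",schiff_base,FALSE,
89,Vanillin,schiff_base,FALSE,
90,Methyl salicylate,none,FALSE,
91,Benzaldehyde,schiff_base,FALSE,
92,Phenoxyethanol,none,FALSE,
93,4-Aminobenzoic acid,none,FALSE,
94,1-Butanol,none,FALSE,
95,Diethyl phthalate,none,FALSE,
96,Dimethylsulfoxide,none,FALSE,
97,Glycerol,none,FALSE,
98,Hexane,none,FALSE,
99,Lactic acid,none,FALSE,
100,Salicylic acid,none,FALSE,
101,Sodium lauryl sulfate,none,FALSE,
102,Tocopherol,michael_acceptor,TRUE,
103,Xylene,none,FALSE,
104,Phenol,none,FALSE,
105,Tween 80,none,FALSE,
106,Octanoic acid,none,FALSE,
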