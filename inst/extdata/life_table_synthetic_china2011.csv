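age,qx
40,0.00226512544642898
41,0.0024312059280599
42,0.00261289524709329
43,0.00281165711507192
44,0.00302909185912392
45,0.00326694904603986
46,0.00352714124777131
47,0.00381175904655096
48,0.00412308738526845
49,0.00446362337652073
50,0.00483609569185173
51,0.0052434856610587
52,0.00568905021999566
53,0.00617634685395596
54,0.00670926069234346
55,0.0072920339187762
56,0.00792929766881179
57,0.00862610659487439
58,0.00938797628437549
59,0.0102209237220549
60,0.0111315109907348
61,0.0121268924053638
62,0.0132148652727025
63,0.0144039244623871
64,0.0157033209633042
65,0.0171231245809751
66,0.0186742909054175
67,0.0203687326429262
68,0.0222193953572428
69,0.0242403376031426
70,0.0264468153555864
71,0.0288553705368473
72,0.0314839233184305
73,0.0343518677195939
74,0.037480169834638
75,0.0408914677909754
76,0.0446101722627131
77,0.0486625660328249
78,0.0530769007030061
79,0.0578834881855489
80,0.0631147840672194
81,0.0688054593022905
82,0.0749924559620904
83,0.0817150219341646
84,0.0890147185197985
85,0.0969353938216185
86,0.105523113645277
87,0.114826040369403
88,0.124894248883766
89,0.135779467286975
90,0.147534728618116
91,0.160213918538499
92,0.173871202673119
93,0.188560316391664
94,0.204333699319484
95,0.22124145702836
96,0.239330133424077
97,0.258641279636175
98,0.27920980909322
99,0.301062134353025
100,0.324214089607284
101,0.348668654061756
102,0.374413506046038
103,0.40141845608057
104,0.429632829396164
105,1
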