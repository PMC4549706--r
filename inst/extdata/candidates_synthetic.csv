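compound,series,site,group,substituent,label,ddG_cal,MW,ClogP,HBA,HBD,ROB,ARB,synthesizable,ki_nM
2,1,4,a,-F,1-4a,-0.95,408.1,4.1,5,0,7,15,TRUE,60.47
3,1,4,b,-Cl,1-4b,0.944,412.2,4,6,0,7,15,TRUE,1449.85
4,1,4,c,-Br,1-4c,-1.258,416.3,3.9,4,0,7,15,TRUE,NA
5,1,4,d,-NO2,1-4d,0.637,420.4,3.8,5,0,7,15,TRUE,NA
6,1,4,e,-CH3,1-4e,-1.521,424.5,3.7,6,0,7,15,TRUE,23.21
7,1,4,f,-CF3,1-4f,0.33,428.6,3.6,4,0,7,15,TRUE,517.65
8,1,4,g,-OCH3,1-4g,-1.804,432.7,3.5,5,0,7,15,TRUE,NA
9,1,4,h,-OH,1-4h,0.022,436.8,3.4,6,1,7,15,TRUE,NA
10,1,4,i,-NH2,1-4i,-2.087,440.9,3.3,4,1,7,15,TRUE,8.98
11,1,4,j,-COOH,1-4j,-0.285,445,3.2,5,1,7,15,TRUE,184.51
12,1,5,a,-F,1-5a,-2.37,415.1,4.35,5,0,8,15,TRUE,NA
13,1,5,b,-Cl,1-5b,-0.592,419.2,4.25,6,0,8,15,TRUE,NA
14,1,5,c,-Br,1-5c,-2.653,423.3,4.15,4,0,8,15,TRUE,3.48
15,1,5,d,-NO2,1-5d,-0.899,427.4,4.05,5,0,8,15,TRUE,65.88
16,1,5,e,-CH3,1-5e,0.995,431.5,3.95,6,0,8,15,TRUE,NA
17,1,5,f,-CF3,1-5f,-1.206,435.6,3.85,4,0,8,15,TRUE,NA
18,1,5,g,-OCH3,1-5g,0.688,439.7,3.75,5,0,8,15,TRUE,943.69
19,1,5,h,-OH,1-5h,-1.474,443.8,3.65,6,1,8,15,TRUE,25.11
20,1,5,i,-NH2,1-5i,0.381,447.9,3.55,4,1,8,15,TRUE,NA
21,1,5,j,-COOH,1-5j,-1.757,452,3.45,5,1,8,15,TRUE,NA
22,1,6,a,-F,1-6a,0.074,422.1,4.6,5,0,6,15,FALSE,336.93
23,1,6,b,-Cl,1-6b,-2.04,426.2,4.5,6,0,6,15,FALSE,9.72
24,1,6,c,-Br,1-6c,-0.234,430.3,4.4,4,0,6,15,FALSE,NA
25,1,6,d,-NO2,1-6d,-2.323,434.4,4.3,5,0,6,15,FALSE,NA
26,1,6,e,-CH3,1-6e,-0.541,438.5,4.2,6,0,6,15,FALSE,120.09
27,1,6,f,-CF3,1-6f,-2.606,442.6,4.1,4,0,6,15,FALSE,3.76
28,1,6,g,-OCH3,1-6g,-0.848,446.7,4,5,0,6,15,FALSE,NA
29,1,6,h,-OH,1-6h,1.046,450.8,3.9,6,1,6,15,FALSE,NA
30,1,6,i,-NH2,1-6i,-1.155,454.9,3.8,4,1,6,15,FALSE,42.88
31,1,6,j,-COOH,1-6j,0.739,459,3.7,5,1,6,15,FALSE,1027.98
32,1,7,a,-F,1-7a,-1.427,429.1,4.85,5,0,7,15,FALSE,NA
33,1,7,b,-Cl,1-7b,0.432,433.2,4.75,6,0,7,15,FALSE,NA
34,1,7,c,-Br,1-7c,-1.71,437.3,4.65,4,0,7,15,FALSE,16.9
35,1,7,d,-NO2,1-7d,0.125,441.4,4.55,5,0,7,15,FALSE,367.02
36,1,7,e,-CH3,1-7e,-1.993,445.5,4.45,6,0,7,15,FALSE,NA
37,1,7,f,-CF3,1-7f,-0.182,449.6,4.35,4,0,7,15,FALSE,NA
38,1,7,g,-OCH3,1-7g,-2.276,453.7,4.25,5,0,7,15,FALSE,6.54
39,1,7,h,-OH,1-7h,-0.49,457.8,4.15,6,1,7,15,FALSE,130.82
40,1,7,i,-NH2,1-7i,-2.559,461.9,4.05,4,1,7,15,FALSE,NA
41,1,7,j,-COOH,1-7j,-0.797,466,3.95,5,1,7,15,FALSE,NA
42,2,4,a,-F,2-4a,1.098,408.1,4.1,5,0,7,16,TRUE,1877.2
43,2,4,b,-Cl,2-4b,-1.104,412.2,4,6,0,7,16,TRUE,NA
44,2,4,c,-Br,2-4c,0.79,416.3,3.9,4,0,7,16,TRUE,NA
45,2,4,d,-NO2,2-4d,-1.38,420.4,3.8,5,0,7,16,TRUE,NA
46,2,4,e,-CH3,2-4e,0.483,424.5,3.7,6,0,7,16,TRUE,NA
47,2,4,f,-CF3,2-4f,-1.663,428.6,3.6,4,0,7,16,TRUE,NA
48,2,4,g,-OCH3,2-4g,0.176,432.7,3.5,5,0,7,16,TRUE,NA
49,2,4,h,-OH,2-4h,-1.946,436.8,3.4,6,1,7,16,TRUE,NA
50,2,4,i,-NH2,2-4i,-0.131,440.9,3.3,4,1,7,16,TRUE,NA
51,2,4,j,-COOH,2-4j,-2.229,445,3.2,5,1,7,16,TRUE,NA
52,2,5,a,-F,2-5a,-0.438,415.1,4.35,5,0,8,16,TRUE,NA
53,2,5,b,-Cl,2-5b,-2.511,419.2,4.25,6,0,8,16,TRUE,NA
54,2,5,c,-Br,2-5c,-0.746,423.3,4.15,4,0,8,16,TRUE,NA
55,2,5,d,-NO2,2-5d,1.149,427.4,4.05,5,0,8,16,TRUE,NA
56,2,5,e,-CH3,2-5e,-1.053,431.5,3.95,6,0,8,16,TRUE,NA
57,2,5,f,-CF3,2-5f,0.842,435.6,3.85,4,0,8,16,TRUE,NA
58,2,5,g,-OCH3,2-5g,-1.36,439.7,3.75,5,0,8,16,TRUE,NA
59,2,5,h,-OH,2-5h,0.534,443.8,3.65,6,1,8,16,TRUE,NA
60,2,5,i,-NH2,2-5i,-1.616,447.9,3.55,4,1,8,16,TRUE,NA
61,2,5,j,-COOH,2-5j,0.227,452,3.45,5,1,8,16,TRUE,NA
62,2,6,a,-F,2-6a,-1.899,422.1,4.6,5,0,6,16,FALSE,NA
63,2,6,b,-Cl,2-6b,-0.08,426.2,4.5,6,0,6,16,FALSE,NA
64,2,6,c,-Br,2-6c,-2.181,430.3,4.4,4,0,6,16,FALSE,NA
65,2,6,d,-NO2,2-6d,-0.387,434.4,4.3,5,0,6,16,FALSE,NA
66,2,6,e,-CH3,2-6e,-2.464,438.5,4.2,6,0,6,16,FALSE,NA
67,2,6,f,-CF3,2-6f,-0.694,442.6,4.1,4,0,6,16,FALSE,NA
68,2,6,g,-OCH3,2-6g,1.2,446.7,4,5,0,6,16,FALSE,NA
69,2,6,h,-OH,2-6h,-1.002,450.8,3.9,6,1,6,16,FALSE,NA
70,2,6,i,-NH2,2-6i,0.893,454.9,3.8,4,1,6,16,FALSE,NA
71,2,6,j,-COOH,2-6j,-1.309,459,3.7,5,1,6,16,FALSE,NA
72,2,7,a,-F,2-7a,0.586,429.1,4.85,5,0,7,16,FALSE,NA
73,2,7,b,-Cl,2-7b,-1.569,433.2,4.75,6,0,7,16,FALSE,NA
74,2,7,c,-Br,2-7c,0.278,437.3,4.65,4,0,7,16,FALSE,NA
75,2,7,d,-NO2,2-7d,-1.851,441.4,4.55,5,0,7,16,FALSE,NA
76,2,7,e,-CH3,2-7e,-0.029,445.5,4.45,6,0,7,16,FALSE,NA
77,2,7,f,-CF3,2-7f,-2.134,449.6,4.35,4,0,7,16,FALSE,NA
78,2,7,g,-OCH3,2-7g,-0.336,453.7,4.25,5,0,7,16,FALSE,NA
79,2,7,h,-OH,2-7h,-2.417,457.8,4.15,6,1,7,16,FALSE,NA
80,2,7,i,-NH2,2-7i,-0.643,461.9,4.05,4,1,7,16,FALSE,NA
81,2,7,j,-COOH,2-7j,-2.7,466,3.95,5,1,7,16,FALSE,NA
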