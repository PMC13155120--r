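code,category
B0101,Nucleic acid biosynthesis
B0102,Nucleic acid biosynthesis
B0103,Nucleic acid biosynthesis
B0211,Amino acid biosynthesis
B0212,Amino acid biosynthesis
B0301,Carbohydrate biosynthesis
B0302,Carbohydrate biosynthesis
B0303,Carbohydrate biosynthesis
B0304,Carbohydrate biosynthesis
B0305,Carbohydrate biosynthesis
B0306,Carbohydrate biosynthesis
B0307,Carbohydrate biosynthesis
B0308,Carbohydrate biosynthesis
B0309,Carbohydrate biosynthesis
B0310,Carbohydrate biosynthesis
B0311,Carbohydrate biosynthesis
B0312,Carbohydrate biosynthesis
B0313,Carbohydrate biosynthesis
B0314,Carbohydrate biosynthesis
B0315,Carbohydrate biosynthesis
B0316,Carbohydrate biosynthesis
B0317,Carbohydrate biosynthesis
B0318,Carbohydrate biosynthesis
B0319,Carbohydrate biosynthesis
B0320,Carbohydrate biosynthesis
B0321,Carbohydrate biosynthesis
B0322,Carbohydrate biosynthesis
B0323,Carbohydrate biosynthesis
B0324,Carbohydrate biosynthesis
B0325,Carbohydrate biosynthesis
B0326,Carbohydrate biosynthesis
B0327,Carbohydrate biosynthesis
B0328,Carbohydrate biosynthesis
B0329,Carbohydrate biosynthesis
B0330,Carbohydrate biosynthesis
B0331,Carbohydrate biosynthesis
B0332,Carbohydrate biosynthesis
B0333,Carbohydrate biosynthesis
B0334,Carbohydrate biosynthesis
B0335,Carbohydrate biosynthesis
B0336,Carbohydrate biosynthesis
B0337,Carbohydrate biosynthesis
B0338,Carbohydrate biosynthesis
B0339,Carbohydrate biosynthesis
B0401,SCFA biosynthesis
B0402,SCFA biosynthesis
B0403,SCFA biosynthesis
B0501,Lipid biosynthesis
B0502,Lipid biosynthesis
B0503,Lipid biosynthesis
B0504,Lipid biosynthesis
B0505,Lipid biosynthesis
B0506,Lipid biosynthesis
B0507,Lipid biosynthesis
B0508,Lipid biosynthesis
B0509,Lipid biosynthesis
B0510,Lipid biosynthesis
B0511,Lipid biosynthesis
B0512,Lipid biosynthesis
B0513,Lipid biosynthesis
B0514,Lipid biosynthesis
B0515,Lipid biosynthesis
B0516,Lipid biosynthesis
B0517,Lipid biosynthesis
B0518,Lipid biosynthesis
B0519,Lipid biosynthesis
B0520,Lipid biosynthesis
B0521,Lipid biosynthesis
B0522,Lipid biosynthesis
B0523,Lipid biosynthesis
B0524,Lipid biosynthesis
B0525,Lipid biosynthesis
B0526,Lipid biosynthesis
B0527,Lipid biosynthesis
B0528,Lipid biosynthesis
B0529,Lipid biosynthesis
B0530,Lipid biosynthesis
B0531,Lipid biosynthesis
B0532,Lipid biosynthesis
B0533,Lipid biosynthesis
B0534,Lipid biosynthesis
B0535,Lipid biosynthesis
B0536,Lipid biosynthesis
B0537,Lipid biosynthesis
B0538,Lipid biosynthesis
B0539,Lipid biosynthesis
B0701,Vitamin biosynthesis
B0702,Vitamin biosynthesis
B0801,Aromatic compound biosynthesis
B0805,Aromatic compound biosynthesis
D0101,Polysaccharide degradation
D0102,Polysaccharide degradation
D0201,Sugar degradation
D0202,Sugar degradation
D0203,Sugar degradation
D0204,Sugar degradation
D0205,Sugar degradation
D0206,Sugar degradation
D0207,Sugar degradation
D0208,Sugar degradation
D0209,Sugar degradation
D0210,Sugar degradation
D0211,Sugar degradation
D0212,Sugar degradation
D0213,Sugar degradation
D0214,Sugar degradation
D0215,Sugar degradation
D0216,Sugar degradation
D0217,Sugar degradation
D0218,Sugar degradation
D0219,Sugar degradation
D0220,Sugar degradation
D0221,Sugar degradation
D0222,Sugar degradation
D0223,Sugar degradation
D0224,Sugar degradation
D0225,Sugar degradation
D0226,Sugar degradation
D0227,Sugar degradation
D0228,Sugar degradation
D0229,Sugar degradation
D0230,Sugar degradation
D0231,Sugar degradation
D0232,Sugar degradation
D0233,Sugar degradation
D0234,Sugar degradation
D0235,Sugar degradation
D0236,Sugar degradation
D0237,Sugar degradation
D0238,Sugar degradation
D0509,Amino acid degradation
D0510,Amino acid degradation
D0701,Xenobiotic degradation
D0702,Xenobiotic degradation
D0703,Xenobiotic degradation
D0704,Xenobiotic degradation
D0705,Xenobiotic degradation
D0706,Xenobiotic degradation
D0707,Xenobiotic degradation
D0708,Xenobiotic degradation
D0709,Xenobiotic degradation
D0710,Xenobiotic degradation
D0711,Xenobiotic degradation
D0712,Xenobiotic degradation
D0713,Xenobiotic degradation
D0714,Xenobiotic degradation
D0715,Xenobiotic degradation
D0716,Xenobiotic degradation
D0717,Xenobiotic degradation
D0718,Xenobiotic degradation
D0719,Xenobiotic degradation
D0720,Xenobiotic degradation
D0721,Xenobiotic degradation
D0722,Xenobiotic degradation
D0723,Xenobiotic degradation
D0724,Xenobiotic degradation
D0725,Xenobiotic degradation
D0726,Xenobiotic degradation
D0727,Xenobiotic degradation
D0728,Xenobiotic degradation
D0729,Xenobiotic degradation
D0730,Xenobiotic degradation
D0731,Xenobiotic degradation
D0732,Xenobiotic degradation
D0733,Xenobiotic degradation
D0734,Xenobiotic degradation
D0735,Xenobiotic degradation
D0736,Xenobiotic degradation
D0737,Xenobiotic degradation
D0738,Xenobiotic degradation
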