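condition	category	patients
Phenylketonuria	AAMD	21
Mild hyperphenylalaninemia	AAMD	21
Hypermethioninemia	AAMD	13
Citrullinemia type II	AAMD	7
Tetrahydrobiopterin deficiency	AAMD	6
Tyrosinemia	AAMD	4
Ornithine transcarbamylase deficiency	AAMD	3
Citrullinemia type I	AAMD	2
Maple syrup urine disease	AAMD	1
Argininosuccinate aciduria	AAMD	1
3-Methylcrotonyl-CoA carboxylase deficiency	OAMD	12
Methylmalonic acidemia	OAMD	10
Isobutyryl coa dehydrogenase deficiency	OAMD	3
Isovaleric acidemia	OAMD	2
Malonic acidemia	OAMD	1
2-Methylbutyrylglycinuria	OAMD	1
Propionic acidemia	OAMD	1
Primary carnitine uptake defect	FAMD	15
Short chain acyl-CoA dehydrogenase deficiency	FAMD	14
Very long chain acyl-CoA dehydrogenase deficiency	FAMD	6
Medium chain acyl-CoA dehydrogenase deficiency	FAMD	5
Glutaric aciduria type I	FAMD	4
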