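variable	stratum	unaffected	patients
gender	Male	210273	86
gender	Female	191194	65
gender	No record	41	0
gestational_age	<32	1915	0
gestational_age	32~36	18652	7
gestational_age	>37	379861	146
gestational_age	No record	1232	0
birth_weight	<1500	607	0
birth_weight	1500-1999	1986	0
birth_weight	2000-2499	9904	4
birth_weight	>2500	377858	149
birth_weight	No record	11305	0
fetus_number	Singleton	398649	152
fetus_number	Twins	2992	1
fetus_number	Triplet	19	0
register_region	Suzhou	229793	91
register_region	Others	171867	62
register_region	No record	0	0
household_registration	Urban	245863	102
household_registration	Rural	155797	51
household_registration	No record	0	0
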