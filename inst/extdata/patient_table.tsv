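sample_id	breed	sex	age_years	subtype	location	grade	cluster
T1860	Cock-a-poo	Male	13.5	PNST	Neck	II	H1
T1921	Golden Retriever	Female	11.1	PNST	Flank	I	H1
T2063	Mix	Female	10.2	PNST	Thigh	II	H1
T148	Mix	Male	14.8	PNST	Hock	I	H1
T218	Mix	Female	11.5	PNST	Hip	II	H1
T230	Mix	Female	13.3	PNST	Knee region	I	H1
T311	Mix	Male	7.5	PNST	Inguinal region	I	H1
T320	Mix	Male	15.5	PNST	Flank	II	H1
T336	Mix	Female	11.3	PNST	Rib region	II	H1
T344	Basset Hound	Female	10.8	PNST	Humerus	I	H1
T697	Labrador Retriever	Female	8.9	PNST	Thorax	III	H1
T1238	Labrador Retriever	Male	9.1	FSA	Hock	III	H2
T167	Mix	Male	8.6	FSA	Cranial sternum	III	H2
T1891	Labrador Retriever	Male	9.7	FSA	Femur	II	H2
T1989	Labrador Retriever	Female	11.1	FSA	Neck	II	H2
T416	Alaskan Malamute	Male	10.2	FSA	Elbow joint	III	H2
T479	German Shepherd	Female	9.3	PNST	Hip	II	H2
T738	Pointer	Male	5.8	PNST	Tarsus	III	H2
T1124	Greyhound	Male	8.3	FSA	Side, lateral	III	H3
T1407	Mix	Male	3.9	FSA	Maxilla	III	H3
T1490	Golden Retriever	Male	5.4	FSA	Hip	III	H3
T1834	Mix	Male	12.6	FSA	Mandible	III	H3
T232	Poodle	Male	6.9	PNST	Femur	III	H3
T1292	Beagle	Male	12.4	FSA	Maxilla	III	H4
T1462	Labrador Retriever	Male	11.9	FSA	Thigh	III	H4
T1585	Beagle	Female	10.0	FSA	Abdomen	III	H4
T1923	Siberian Husky	Male	10.5	UPS	Rib region	II	H4
T282	Border Collie	Female	12.5	FSA	Lip	II	H4
T485	Mix	Female	6.3	FSA	Maxilla	I	H4
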