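genus	publication_count	group	env_flags
Bacillus	25		Human;Soil;Indoor
Pseudomonas	22		Human;Soil;Freshwater
Staphylococcus	21		Human;Human_skin;Indoor
Mycobacterium	9		Human;Aquatic;Indoor
Clostridium	8		Human;Human_gut;Soil
Corynebacterium	7		Human;Human_skin
Enterococcus	6		Human;Human_gut
Rarissima	2		Soil
Ignotum	1
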