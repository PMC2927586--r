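key	value	note
positive_lines	1885	positive transgenic lines recovered, over 266 constructs
lines_in_soil	1457	plants surviving transfer from selection plates to soil (239 genes)
expressing_plants	761	plants with visible GFP expression (150 promoters)
images_recorded	2287	GFP expression images captured
po_assignments	3371	PO code assignments over all images
category_consistent_multi	112	promoters with the same pattern in two or more lines
category_single_line_expressing	19	promoters with a single recovered line, expressing
category_single_expressing_of_many	14	promoters with several lines but one expressing
category_inconsistent	5	promoters with disagreeing patterns across lines
independent_dip_consistent	79	consistent promoters confirmed across separate floral dips
gfp_negative_pcr_plants	256	GFP-negative plants checked by leaf PCR (89 promoters)
gfp_negative_pcr_lines	423	GFP-negative lines checked by leaf PCR (83 promoters)
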