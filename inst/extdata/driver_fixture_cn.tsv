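event_id	gene	cn_total	start	end	ploidy	expression_z	expected_driver	expected_rule
cn01	WT1	0	1000000	1500000	diploid	NA	TRUE	homozygous_deletion
cn02	WT1	0	1000000	2200000	diploid	NA	FALSE	
cn03	MYCN	5	1000000	1800000	diploid	NA	TRUE	amplification
cn04	MYCN	4	1000000	1800000	diploid	NA	FALSE	
cn05	MYCN	4	1000000	1800000	diploid	3.5	TRUE	amplification_expression_rescue
cn06	MYCN	9	1000000	1800000	tetraploid	NA	TRUE	amplification
cn07	MYCN	8	1000000	1800000	tetraploid	NA	FALSE	
cn08	WT1	5	1000000	1800000	diploid	NA	FALSE	
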