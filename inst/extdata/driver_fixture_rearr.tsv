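event_id	gene	partner_gene	hit	expression_z	expected_driver	expected_rule
rr01	YWHAE	NUTM2B	NA	NA	TRUE	fusion
rr02	WT1	NA	footprint	NA	TRUE	footprint_disruption
rr03	MYCN	NA	regulatory	4	TRUE	regulatory_expression_rescue
rr04	MYCN	NA	regulatory	1	FALSE	
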