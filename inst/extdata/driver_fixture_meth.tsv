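event_id	gene	beta_z	expr_z	expected_driver	expected_rule
me01	TP53	3.5	-3.2	TRUE	promoter_hypermethylation
me02	TP53	3.5	0	FALSE	
me03	WT1	2.9	-4	FALSE	
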