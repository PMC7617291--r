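event_id	gene	consequence	protein_pos	expected_driver	expected_rule
sv01	CTNNB1	missense	45	TRUE	hotspot
sv02	CTNNB1	missense	33	FALSE	
sv03	WT1	truncating	NA	TRUE	truncating
sv04	CTNNB1	truncating	NA	FALSE	
sv05	PIK3CA	inframe	545	TRUE	hotspot
sv06	WT1	missense	45	FALSE	
sv07	NOVELGENE	missense	100	FALSE	
sv08	TP53	truncating	NA	TRUE	truncating
sv09	MYCN	splice_region	NA	FALSE	
sv10	TERT	promoter	228	TRUE	always_keep
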