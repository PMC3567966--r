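bin_id	start_marker	end_marker	phenotype_keywords
IL1-1	C1M1S	C1M1E	
IL1-2	C1M2S	C1M2E	
IL1-3	C1M3S	C1M3E	
IL1-4	C1M4S	C1M4E	
IL2-1	C2M1S	C2M1E	
IL2-2	C2M2S	C2M2E	fruit weight QTL
IL2-3	C2M3S	C2M3E	
IL2-4	C2M4S	C2M4E	
IL3-1	C3M1S	C3M1E	
IL3-2	C3M2S	C3M2E	
IL3-3	C3M3S	C3M3E	
IL3-4	C3M4S	C3M4E	
IL4-1	C4M1S	C4M1E	
IL4-2	C4M2S	C4M2E	
IL4-3-2	C4M3S	C4M3E	fruit color QTL
IL4-4	C4M4S	C4M4E	
IL5-1	C5M1S	C5M1E	
IL5-2	C5M2S	C5M2E	
IL5-3	C5M3S	C5M3E	
IL5-4	C5M4S	C5M4E	
IL6-1	C6M1S	C6M1E	
IL6-2	C6M2S	C6M2E	
IL6-3	C6M3S	C6M3E	
IL6-4	C6M4S	C6M4E	
IL7-1	C7M1S	C7M1E	
IL7-2	C7M2S	C7M2E	
IL7-3	C7M3S	C7M3E	
IL7-4	C7M4S	C7M4E	
IL8-1	C8M1S	C8M1E	
IL8-2	C8M2S	C8M2E	
IL8-3	C8M3S	C8M3E	
IL8-4	C8M4S	C8M4E	
IL9-1	C9M1S	C9M1E	soluble solids QTL
IL9-2	C9M2S	C9M2E	
IL9-3	C9M3S	C9M3E	
IL9-4	C9M4S	C9M4E	
IL10-1	C10M1S	C10M1E	
IL10-2	C10M2S	C10M2E	
IL10-3	C10M3S	C10M3E	
IL10-4	C10M4S	C10M4E	
IL11-1	C11M1S	C11M1E	
IL11-2	C11M2S	C11M2E	
IL11-3	C11M3S	C11M3E	
IL11-4	C11M4S	C11M4E	
IL12-1	C12M1S	C12M1E	
IL12-2	C12M2S	C12M2E	
IL12-3	C12M3S	C12M3E	
IL12-4	C12M4S	C12M4E	
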