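mz	compound	node_ids	fragment_of
33.033	methanol	C00132	
31.018	formaldehyde	C00067	
47.013	formate	C00058	
60.081	trimethylamine	C00565	
46.065	dimethylamine	C00543	
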