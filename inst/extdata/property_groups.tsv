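base	category	distance	members
charge_any	polarity	any	
charge_any	polarity	3-4	
charge_any	polarity	4-5	
charge_negative	polarity	any	
charge_negative	polarity	3	
charge_negative	polarity	4	
charge_positive	polarity	any	
charge_positive	polarity	4	
charge_positive	polarity	4-5	
charge_positive	polarity	5	
charge_positive	polarity	5-6	
charge_positive	polarity	6	
hbond_donor	polarity	any	
hbond_donor	polarity	2	
hbond_donor	polarity	3	
hbond_donor	polarity	4	
hbond_donor	polarity	5	
hbond_donor	polarity	6	
hbond_donor	polarity	2-3	
hbond_donor	polarity	3-4	
hbond_donor	polarity	4-5	
hbond_donor	polarity	5-6	
hbond_acceptor	polarity	any	
hbond_acceptor	polarity	2	
hbond_acceptor	polarity	3	
hbond_acceptor	polarity	4	
hbond_acceptor	polarity	6	
hbond_acceptor	polarity	2-3	
hbond_acceptor	polarity	3-4	
hbond_any	polarity	any	
hbond_any	polarity	2-3	
hbond_any	polarity	3-4	
hbond_any	polarity	4-5	
hbond_any	polarity	5-6	
aromatic	polarity	any	
aromatic	polarity	4	
aromatic	polarity	5	
aromatic	polarity	6	
aromatic	polarity	4-5	
aromatic	polarity	5-6	
aliphatic	polarity	any	
aliphatic	polarity	1	
aliphatic	polarity	2	
aliphatic	polarity	3	
aliphatic	polarity	4	
aliphatic	polarity	1-2	
aliphatic	polarity	2-3	
aliphatic	polarity	3-4	
size_tiny	size	any	GAS
size_small	size	any	CTPNDV
size_medium	size	any	MILEQHK
size_large	size	any	RFYW
helix_high	helical_propensity	any	ALMEQKRH
helix_medium	helical_propensity	any	IVFWYDNTSC
helix_low	helical_propensity	any	GP
helix_compatible	helical_propensity	any	ARNDCQEHILKMFSTWYV
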