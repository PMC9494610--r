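junction_aa	v_call	j_call	productive	duplicate_count
CASSLGQAYEQYF	TRBV20-1	TRBJ2-7	T	42
CASSLGQAYEQYF	TRBV20-1	TRBJ2-7	T	3
CASSPDRNTGELFF	TRBV6-2/6-3	TRBJ2-2	T	17
CASSQETQGRNYGYTF	TRBV4-1	TRBJ1-2	T	9
CASRGTGDSNQPQHF	TRBV12-3	TRBJ1-5	T	5
CASS*DRNTGELFF	TRBV6-2	TRBJ2-2	F	2
CASSYSTGSTDTQYF	TRBV6-5	TRBJ2-3	T	1
CASSLAGVDTEAFF	TRBV27	TRBJ1-1	T	1
CASSFGREQPQHF	TRBV5-1	TRBJ1-5	T	1
CASSEGLAGVGETQYF	TRBV2	TRBJ2-5	T	6
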