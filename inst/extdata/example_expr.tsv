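mirna_id	S1	S2	S3
miR-149-3p	1000	2100	950
miR-2861	2050	4100	2000
miR-4463	4100	8000	4050
miR-sim-0001	120	260	25
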