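sample_id	group	control_source	stage	age	sex	background
S1	case		I	64	male	30
S2	case		III	71	male	28
S3	control	noncancer1		58	female	32
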