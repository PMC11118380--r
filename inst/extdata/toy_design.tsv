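sample_id	condition	replicate_set
pH74_r1	pH74	1
pH74_LPS_r1	pH74_LPS	1
pH65_r1	pH65	1
pH65_LPS_r1	pH65_LPS	1
pH74_r2	pH74	2
pH74_LPS_r2	pH74_LPS	2
pH65_r2	pH65	2
pH65_LPS_r2	pH65_LPS	2
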