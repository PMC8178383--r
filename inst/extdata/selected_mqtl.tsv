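mqtl_id	n_qtl	ci_width	span_mb	mean_pve
durumMQTL2B.1	5	0.8	1.4	0.41
durumMQTL2B.8	5	0.4	0.5	0.10
durumMQTL3A.4	5	2.6	1.4	0.11
durumMQTL3B.1	7	1.7	0.7	0.11
durumMQTL3B.5	5	4.4	4.6	0.13
durumMQTL6A.3	6	3.5	1.3	0.10
durumMQTL6A.4	6	0.4	0.3	0.10
durumMQTL6B.1	5	4.5	4.1	0.10
durumMQTL7A.1	5	2.3	4.6	0.22
durumMQTL7B.9	7	0.1	0.8	0.19
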