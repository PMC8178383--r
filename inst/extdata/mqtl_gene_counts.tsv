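mqtl_id	genes_durum	genes_bread
durumMQTL2B.1	29	42
durumMQTL2B.8	8	11
durumMQTL3A.4	24	32
durumMQTL3B.1	20	22
durumMQTL3B.5	111	45
durumMQTL6A.3	20	8
durumMQTL6A.4	16	4
durumMQTL6B.1	107	69
durumMQTL7A.1	104	69
durumMQTL7B.9	17	24
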