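dataset	DCRA_M	LSTM-CapsAtt	DCRA_E	DNNSN	LSTM	GELM
D1	1	2	3	5	4	6
D2	1	2	3	4	6	5
D3	1	2	3	4	5	6
D4	2	1	4	3	6	5
D5	1	2	3	6	5	4
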