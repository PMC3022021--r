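step	gene	ec
1	lysC	2.7.2.4
2	asd	1.2.1.11
3	dapA	4.2.1.52
4	dapB	1.3.1.26
5	dapD	2.3.1.89|2.3.1.117
6	araT	2.6.1.57
7	hipO3	3.5.1.47
8	dapF	5.1.1.7
9	lysA	4.1.1.20
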