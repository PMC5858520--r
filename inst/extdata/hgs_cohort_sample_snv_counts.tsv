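patient	Ov1	Ov2	Ov3	Om1	Om2	Om3	Bw1	Bw2	Bw3
Patient1	98	91	98	104	100	85	99	102	103
Patient2	98	87	91	102	105	90	110	105	117
Patient3	82	81	73	64	60	60	62	70	61
Patient4	104	108	105	77	72	74	112	109	103
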