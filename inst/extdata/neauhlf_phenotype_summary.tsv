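trait	line	n	mean	sd
AFW	lean	272	30.09	10.07
AFW	fat	203	110.29	27.87
AFP	lean	272	1.23	0.37
AFP	fat	203	4.62	1.10
BW7	lean	272	2417.52	244.64
BW7	fat	203	2384.33	201.42
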