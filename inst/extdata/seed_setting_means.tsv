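stage	genotype	mean_percent
D4	Xun928	99.3
D4	Lx9801	96.3
D4	Zong3	100.0
D4	Xun928xZong3	100.0
D4	Lx9801xZong3	100.0
D6	Xun928	97.4
D6	Lx9801	89.3
D6	Zong3	100.0
D6	Xun928xZong3	100.0
D6	Lx9801xZong3	99.6
D8	Xun928	95.0
D8	Lx9801	78.8
D8	Zong3	100.0
D8	Xun928xZong3	95.6
D8	Lx9801xZong3	80.3
D10	Xun928	26.0
D10	Lx9801	16.3
D10	Zong3	100.0
D10	Xun928xZong3	84.6
D10	Lx9801xZong3	70.4
D12	Xun928	13.5
D12	Lx9801	1.9
D12	Zong3	100.0
D12	Xun928xZong3	80.2
D12	Lx9801xZong3	66.9
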