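id	class	intensity	peptides
MaSp1c	MaSp	34307000	91
MaSp1b	MaSp	9760000	80
SpiCE-DS1	SpiCE-DS	2618000	22
MaSp1a	MaSp	6656000	64
MaSp-like	MaSp	4104000	57
MaSp2a	MaSp	4346520	116
MaSp2b	MaSp	2734614	89
MaSp2c	MaSp	1788845	71
MaSp2d	MaSp	1983360	96
MaSp1d	MaSp	965637	57
MiSp1	MiSp	1500336	108
SpiCE-DS2	SpiCE-DS	205038	18
SpiCE-DS3	SpiCE-DS	373640	40
SpiCE-DS4	SpiCE-DS	84249	11
SpiCE-DS5	SpiCE-DS	131901	21
SpiCE-DS6	SpiCE-DS	154500	30
SpiCE-DS7	SpiCE-DS	71791	17
SpiCE-DS8	SpiCE-DS	121205	35
SpiCE-DS9	SpiCE-DS	113600	40
SpiCE-DS10	SpiCE-DS	76857	33
SpiCE-DS11	SpiCE-DS	36271	19
SpiCE-DS12	SpiCE-DS	36018	23
SpiCE-DS13	SpiCE-DS	44940	35
SpiCE-DS14	SpiCE-DS	17901	17
SpiCE-DS15	SpiCE-DS	31068	36
GDH	GDH	17700	25
mucin-19	mucin-19	15660	27
venom protein	venom protein	15232.0000000009	32
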