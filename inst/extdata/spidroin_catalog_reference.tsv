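gene_id	type	confidence	completeness
MaSp-1	MaSp	1	full-length
MaSp-2	MaSp	1	full-length
MaSp-3	MaSp	1	full-length
MaSp-4	MaSp	1	full-length
MaSp-5	MaSp	1	full-length
MaSp-6	MaSp	1	full-length
MaSp-7	MaSp	1	full-length
MaSp-8	MaSp	1	full-length
MaSp-9	MaSp	1	full-length
MiSp-1	MiSp	1	full-length
MiSp-2	MiSp	1	full-length
MiSp-3	MiSp	1	full-length
MiSp-4	MiSp	1	full-length
MiSp-5	MiSp	1	full-length
FlSp-1	FlSp	1	full-length
FlSp-2	FlSp	1	full-length
TuSp-1	TuSp	1	full-length
AgSp-1	AgSp	1	full-length
AgSp-2	AgSp	1	full-length
AcSp-1	AcSp	1	full-length
PySp-1	PySp	1	full-length
other-1	other	1	full-length
other-2	other	1	full-length
other-3	other	1	full-length
other-4	other	1	full-length
other-5	other	1	full-length
other-6	other	1	partial
other-7	other	1	partial
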