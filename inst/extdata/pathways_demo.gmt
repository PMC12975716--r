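B cell receptor signaling	synthetic demo set	CD19	MS4A1	CD79A	CD79B	BLNK	SYK
T cell receptor signaling	synthetic demo set	CD3D	CD3E	CD2	LCK	ZAP70	CD8A
interferon response	synthetic demo set	GNLY	NKG7	ISG15	IFIT1	MX1
innate immune response	synthetic demo set	CD14	LYZ	FCN1	TLR4	S100A8
antigen presentation	synthetic demo set	FCER1A	CST3	CLEC9A	HLA-DRA	CD74
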