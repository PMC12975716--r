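# Synthetic demo marker knowledge base (hand-curated toy values, not a
# curated marker database). Columns are tab-separated; list cells use "|".
cell_type	cl_id	broad_markers	narrow_markers	negative_markers	tissues	states	pathways_type	pathways_state	synonyms
B cell	CL:0000236	CD19|MS4A1|CD79A	TCL1A	CD3E	blood	activated@blood:inflammation	B cell receptor signaling	interferon response	B cells|B-cell
T cell	CL:0000084	CD3D|CD3E|CD2	CD8A	CD19	blood		T cell receptor signaling		T cells
NK cell	CL:0000623	GNLY|NKG7|KLRD1		CD14	blood			interferon response	natural killer cell
monocyte	CL:0000576	CD14|LYZ|FCN1		GNLY	blood		innate immune response		monocytes
dendritic cell	CL:0000451	FCER1A|CST3|CLEC9A		LYZ	blood		antigen presentation		DC
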