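# Synthetic demo fragment of a cell-type is_a hierarchy (child<TAB>parent).
CL:0000542	CL:0000000
CL:0000236	CL:0000542
CL:0000084	CL:0000542
CL:0000625	CL:0000084
CL:0000623	CL:0000542
CL:0000576	CL:0000000
CL:0000451	CL:0000000
CL:0000182	CL:0000000
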