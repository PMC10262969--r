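# Published correspondence between five-lineage topology indices (T1-T15)
# and (T_G4, G_DF) relationship labels, as recoverable from reported tree
# classifications. The remaining eight indices are not recoverable.
t_index	tg4	gdf
T1	I	X
T3	III	X
T4	I	R
T7	I	T
T10	II	T
T13	III	T
T14	II	R
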