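# Region and residue-set defaults anchored on human PRPS1 numbering.
# Loop windows are approximate, implementer-chosen spans containing the
# published catalytic residues; edit freely. Interface (bent/parallel dimer)
# and allosteric residue-set membership must be supplied by the user
# (no rows ship for them).
kind	name	start	end	position	expected
reference	PRPS1_HUMAN				
region	flag_region	29	45		
region	regulatory_flexible_loop	88	110		
region	pp_loop	165	175		
region	cf_loop	190	205		
region	r5p_loop	218	230		
set	catalytic			171	D
set	catalytic			194	K
set	catalytic			196	R
set	catalytic			200	N
set	catalytic			225	T
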