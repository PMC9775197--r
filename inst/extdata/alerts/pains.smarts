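# Compact pan-assay interference (PAINS) catalog: representative patterns for
# the most frequent published PAINS families. name<TAB>SMARTS. Editable;
# supply a full catalog file to use a different version.
quinone_A	O=C1C=CC(=O)C=C1
catechol_A	[OX2H]c1ccccc1[OX2H]
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1NC(=S)SC1=[CX3]
hzone_phenol_A	[OX2H]c1ccccc1C=N[NX3]
azo_aryl	c[NX2]=[NX2]c
anil_di_alk_A	c1ccc(cc1)N(C)C
mannich_A	[OX2H]c1ccccc1C[NX3]
ene_one_ene	C=CC(=O)C=C
thio_urea_enamine	[NX3]C(=[SX1])[NX3]c
styrene_nitro	c1ccccc1C=C[NX3+](=O)[O-]
imine_phenol	[OX2H]c1ccccc1C=[NX2]
beta_keto_anhydride	O=C[CX4]C(=O)OC(=O)
alk_aldehyde	[CX4][CX3H1]=[OX1]
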