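# Compact structural-alert catalog in the spirit of the Brenk et al. (2008)
# unwanted-moiety list. name<TAB>SMARTS. Editable; supply a full catalog file
# to use a different version.
oxygen-nitrogen single bond	[NX3;!$([NX3](=[OX1]));!$([NX3+])][OX2]
thiocarbonyl	[#6]=[SX1]
imine	[CX3;!$([CX3][OX2H])]=[NX2;!$([NX2][OX2H])]
Michael acceptor	[CX3]=[CX3][CX3]=[OX1]
hydroxamic acid	[CX3](=[OX1])[NX3][OX2H1]
nitro	[$([NX3](=O)=O),$([NX3+](=[OX1])[OX1-])]
aliphatic long chain	[CH2R0][CH2R0][CH2R0][CH2R0][CH2R0][CH2R0]
coumarin	O=c1ccc2ccccc2o1
catechol	[OX2H]c1ccccc1[OX2H]
thiol	[#16X2H]
aldehyde	[CX3H1](=[OX1])[#6]
acyl halide	[CX3](=[OX1])[F,Cl,Br,I]
alkyl halide	[CX4][Br,I]
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
azide	[NX2]=[NX2+]=[NX1-]
diazonium	[NX2+]#[NX1]
peroxide	[OX2][OX2]
epoxide	C1OC1
aziridine	C1NC1
hydantoin	O=C1NC(=O)CN1
phosphor anhydride	[PX4](=[OX1])[OX2][PX4](=[OX1])
quaternary nitrogen	[NX4+]
crown ether	[OX2R][CX4R][CX4R][OX2R][CX4R][CX4R][OX2R]
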