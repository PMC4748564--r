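# Functional-group vocabulary: name<TAB>SMARTS
# Editable; patterns are matched with symmetry-deduplicated unique matches.
ROH	[CX4][OX2H]
phenol	[c][OX2H]
ROR	[OD2]([#6;!$([#6]=O)])[#6;!$([#6]=O)]
RCOR	[#6][CX3](=O)[#6]
RCHO	[CX3H1](=O)[#6]
RCOOH	[CX3](=O)[OX2H1]
RCOOR	[CX3](=O)[OX2][#6;!$([#6]=O)]
RNH2	[NX3;H2;!$(NC=O);!$(N=O)][#6]
R2NH	[NX3;H1;!$(NC=O);!$(N=O)]([#6])[#6]
R3N	[NX3;H0;!$(NC=O);!$(N=O);!$([N+])]([#6])([#6])[#6]
amide	[NX3][CX3](=[OX1])
RCN	[NX1]#[CX2]
RNO2	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
RSH	[SX2H]
RSR	[SD2]([#6])[#6]
RX	[F,Cl,Br,I]
aromatic_N	[nX2,nX3;!$([n+])]
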