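name,smiles
K3PO4,O=P([O-])([O-])[O-].[K+].[K+].[K+]
K2CO3,[K+].[K+].[O-]C([O-])=O
Cs2CO3,[Cs+].[Cs+].[O-]C([O-])=O
KOtBu,CC(C)(C)[O-].[K+]
NaOtBu,CC(C)(C)[O-].[Na+]
KOH,[K+].[OH-]
NaOH,[Na+].[OH-]
DBU,C1CCC2=NCCCN2CC1
Et3N,CCN(CC)CC
DIPEA,CCN(C(C)C)C(C)C
P4-t-Bu,
P2-Et,
dioxane,C1COCCO1
toluene,Cc1ccccc1
THF,C1CCOC1
DMAc,CC(=O)N(C)C
DMF,CN(C)C=O
DMSO,CS(C)=O
NMP,CN1CCCC1=O
MeCN,CC#N
t-AmOH,CCC(C)(C)O
allyl alcohol,OCC=C
iPrOH,CC(C)O
MeOH,CO
EtOH,CCO
EtOAc,CCOC(C)=O
AcOH,CC(O)=O
water,O
Pd(OAc)2,CC(=O)O[Pd]OC(C)=O
Pd2(dba)3,
PdCl2,Cl[Pd]Cl
CuI,[Cu]I
CuBr,[Cu]Br
Cu2O,
CuOAc,CC(=O)O[Cu]
Pd/C 5%,
Pd/C 10%,
Pd(OH)2/C,
PtO2,O=[Pt]=O
Raney Ni,[Ni]
Rh/Al2O3,
Ru p-cymene,
zinc dust,[Zn]
HCl,Cl
none,
PPh3,c1ccc(cc1)P(c1ccccc1)c1ccccc1
PCy3,C1CCC(CC1)P(C1CCCCC1)C1CCCCC1
PtBu3,CC(C)(C)P(C(C)(C)C)C(C)(C)C
PnBu3,CCCCP(CCCC)CCCC
dppe,c1ccc(cc1)P(CCP(c1ccccc1)c1ccccc1)c1ccccc1
dppb,c1ccc(cc1)P(CCCCP(c1ccccc1)c1ccccc1)c1ccccc1
JohnPhos,CC(C)(C)P(C(C)(C)C)c1ccccc1-c1ccccc1
CyJohnPhos,C1CCC(CC1)P(C1CCCCC1)c1ccccc1-c1ccccc1
SPhos,COc1cccc(OC)c1-c1ccccc1P(C1CCCCC1)C1CCCCC1
XPhos,CC(C)c1cc(C(C)C)cc(C(C)C)c1-c1ccccc1P(C1CCCCC1)C1CCCCC1
BrettPhos,COc1ccc(OC)c(-c2c(C(C)C)cc(C(C)C)cc2C(C)C)c1P(C1CCCCC1)C1CCCCC1
t-BuBrettPhos,COc1ccc(OC)c(-c2c(C(C)C)cc(C(C)C)cc2C(C)C)c1P(C(C)(C)C)C(C)(C)C
RockPhos,COc1ccc(OC)c(-c2c(C(C)C)cc(C(C)C)cc2C(C)C)c1P(C(C)(C)C)C(C)(C)C
BippyPhos,
Xantphos,CC1(C)c2cccc(P(c3ccccc3)c3ccccc3)c2Oc2c(P(c3ccccc3)c3ccccc3)cccc21
phenanthroline,c1cnc2c(c1)ccc1cccnc12
neocuproine,Cc1ccc2ccc3ccc(C)nc3c2n1
DMEDA,CNCCNC
TMEDA,CN(C)CCN(C)C
trans-DACH,NC1CCCCC1N
8-hydroxyquinoline,Oc1cccc2cccnc12
picolinamide,NC(=O)c1ccccn1
L-proline,OC(=O)C1CCCN1
DMPAO,Cc1cccc(C)c1NCC(O)=O
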