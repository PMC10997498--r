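label,metal_source,ligand
BrettPhos Pd G1,Pd G1,BrettPhos
t-BuBrettPhos Pd G1,Pd G1,t-BuBrettPhos
BrettPhos Pd G3,Pd G3,BrettPhos
OMs BrettPhos Pd G3,Pd G3 (OMs),BrettPhos
OMs RockPhos Pd G3,Pd G3 (OMs),RockPhos
RockPhos Pd G3,Pd G3,RockPhos
XPhos Pd G2,Pd G2,XPhos
tBuXPhos Pd G3,Pd G3,tBuXPhos
SPhos Pd G2,Pd G2,SPhos
Xantphos Pd G3,Pd G3,Xantphos
BippyPhos Pd G3,Pd G3,BippyPhos
(dppb)RuCl2AMPY,RuCl2 AMPY,dppb
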