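role,priority,smarts,label
halide,1,c[I],ArI
halide,2,c[Br],ArBr
halide,3,c[Cl],ArCl
nucleophile,1,"[NX3;!H0][CX3]=[OX1]",amide
nucleophile,2,"[nH]",aromatic nitrogen
nucleophile,3,"[NX3;H2;!$([NX3][CX3]=[OX1])]",primary amine
nucleophile,4,"[NX3;H1;!$([NX3][CX3]=[OX1])]",secondary amine
nucleophile,5,"[CX4;H2][OX2;H1]",primary alcohol
nucleophile,6,"[CX4;H1][OX2;H1]",secondary alcohol
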