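variant,affected,unaffected,revel,alphamissense,clinvar
p.R420W,14,10,0.93,0.97,Pathogenic
p.V186M,1,22,0.71,0.56,Uncertain significance
p.R2258C,1,18,0.88,0.91,Uncertain significance
p.I3995V,1,7,0.45,0.33,Likely benign
p.A4723T,1,23,0.66,0.48,Uncertain significance
p.R4959W,1,43,0.81,0.77,Uncertain significance
p.G230C,6,2,0.95,0.99,Pathogenic
p.S2246L,19,6,0.96,0.99,Pathogenic
p.E189D,2,11,0.52,0.41,
p.T415I,3,4,0.74,0.69,
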