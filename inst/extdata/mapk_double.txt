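# Double-layer MAPK phosphorylation cascade (12 species, 18 reactions)
A + E1 -> AE1 ; k1
AE1 -> A + E1 ; k2
AE1 -> E1 + Ap ; k3
E1 + Ap -> ApE1 ; k4
ApE1 -> E1 + Ap ; k5
ApE1 -> E1 + App ; k6
E1 + App -> AppE1 ; k7
AppE1 -> E1 + App ; k8
AppE1 -> E1 + Appp ; k9
Appp + E2 -> ApppE2 ; k10
ApppE2 -> Appp + E2 ; k11
ApppE2 -> App + E2 ; k12
App + E2 -> AppE2 ; k13
AppE2 -> App + E2 ; k14
AppE2 -> Ap + E2 ; k15
Ap + E2 -> ApE2 ; k16
ApE2 -> Ap + E2 ; k17
ApE2 -> A + E2 ; k18
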