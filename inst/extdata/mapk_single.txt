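# Single-layer MAPK phosphorylation cycle (9 species, 12 reactions).
# In the published listing reaction 6 reads "ApE1 -> App" with the kinase not
# released; that drops the enzyme conservation relation and contradicts the
# published rank (6) and critical-fragment count (9), both of which are
# reproduced with the enzyme released, so B6 is written here as
# ApE1 -> App + E1.
A + E1 -> AE1 ; k1
AE1 -> A + E1 ; k2
AE1 -> E1 + Ap ; k3
E1 + Ap -> ApE1 ; k4
ApE1 -> E1 + Ap ; k5
ApE1 -> E1 + App ; k6
App + E2 -> AppE2 ; k7
AppE2 -> App + E2 ; k8
AppE2 -> Ap + E2 ; k9
Ap + E2 -> ApE2 ; k10
ApE2 -> Ap + E2 ; k11
ApE2 -> A + E2 ; k12
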