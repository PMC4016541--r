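# Yeast Cdc42 / cell polarity network, as printed (8 species, 12 reactions).
# B12 is the self-map RDIm -> RDIm exactly as published; see
# cdc42_corrected_b12.txt for the plausible correction RDIm -> RDIc.
Ec -> Em ; k1
Em -> Ec ; k2
Em + RT -> M ; k3
M -> Em + RT ; k4
Em + RD -> Em ; k5
M + RD -> RT + M ; k6
RT -> RD ; k7
Ec + RT -> M ; k8
RDIm -> RD + I ; k9
RD + I -> RDIm ; k10
RDIc -> RDIm ; k11
RDIm -> RDIm ; k12
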