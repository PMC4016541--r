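# Yeast Cdc42 / cell polarity network, corrected variant (8 species, 12
# reactions). Two products dropped in the published listing are restored:
#  - B5 reads "Em + RD -> Em" as printed; the GEF-catalyzed activation
#    produces membrane-bound active Cdc42, Em + RD -> Em + RT (without it the
#    Cdc42 mass conservation is broken and the rank is 6, not the published 5).
#  - B12 reads "RDIm -> RDIm" (a null self-map) as printed; the membrane
#    detachment is RDIm -> RDIc.
# This variant reproduces the published rank (5) and the published count of
# critical fragments at the rank order (35); see cdc42_as_printed.txt for the
# verbatim listing.
Ec -> Em ; k1
Em -> Ec ; k2
Em + RT -> M ; k3
M -> Em + RT ; k4
Em + RD -> Em + RT ; k5
M + RD -> RT + M ; k6
RT -> RD ; k7
Ec + RT -> M ; k8
RDIm -> RD + I ; k9
RD + I -> RDIm ; k10
RDIc -> RDIm ; k11
RDIm -> RDIc ; k12
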