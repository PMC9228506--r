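# Role-tag mapping for CHARMM36-style POPC atom names plus TIP3P water.
# Apply with apply_role_config(topology, this_file).
lipid_P: [P]
lipid_N: [N]
sn1_chain: [C32, C33, C34, C35, C36, C37, C38, C39, C310, C311, C312, C313, C314, C315, C316]
sn2_chain: [C22, C23, C24, C25, C26, C27, C28, C29, C210, C211, C212, C213, C214, C215, C216, C217, C218]
water_O: [OW, OH2]
water_H: [HW1, HW2, H1, H2]
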