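# Standard formation enthalpies at 25 C, kJ/mol (reference data, editable).
# Phases: glucose solid, water liquid, CO2 gas, H+ aqueous (convention 0),
# O2 gas (element, 0), electron (bookkeeping species, defined 0).
species,dHf_kJ_per_mol
glucose,-1273.3
water,-285.83
co2,-393.51
proton,0
oxygen,0
electron,0
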