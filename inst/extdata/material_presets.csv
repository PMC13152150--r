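# calibration envelope: E_cell0=0.8 V, ASR=0.04 Ohm.m2, T=303.15 K, grid 50 pts on [0, 10] A/m2
name,i0,alpha,n,E_eq
platinum,0.0482312713258846,0.5,1,0
graphene,0.0359552374674075,0.5,1,0
carbon_nanotube,0.0252849546028748,0.5,1,0
graphite_felt,0.0164484064573267,0.5,1,0
stainless_steel,0.0111281997292026,0.5,1,0
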