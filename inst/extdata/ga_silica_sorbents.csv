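name,agent,q_fg_mol_per_g,s_bet_m2_per_g,pore_volume_cm3_per_g,pore_diameter_nm
SBA-15,,,770,0.96,5.8
SBA-15-AP,APTMS,1.55e-3,438,0.67,5.4
SBA-15-MAP,MAPTMS,1.42e-3,430,0.67,5.4
SBA-15-DMAP,DMAPTMS,1.30e-3,425,0.68,5.4
SBA-15-AEAP,AEAPTMS,1.47e-3,382,0.66,5.3
Aer,,,181,,
Aer-AP,APTMS,5.63e-4,168,,
Aer-MAP,MAPTMS,4.99e-4,163,,
Aer-DMAP,DMAPTMS,4.32e-4,158,,
Aer-AEAP,AEAPTMS,6.10e-4,149,,
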