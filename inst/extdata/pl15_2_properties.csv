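enzyme,molecular_mass_kda,isoelectric_point,signal_peptide,opt_temperature_c,opt_ph,activity_hp_f_aIII_u_mg,activity_hp_u_mg
BIexoHep,98.9,6.54,SPI,30,6.0,49.89,0.75
BCexoHep,98.5,6.91,SPII,20,8.0,61.86,1.14
BTexoHep,100.3,7.37,SPII,20,8.0,26.75,NA
PAexoHep,98.3,8.83,SPI,10,8.0,24.25,NA
BFexoHep,100.2,9.76,SPI,20,8.0,12.15,NA
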