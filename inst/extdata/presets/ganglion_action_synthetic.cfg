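# Preset: ganglion / action -- SYNTHETIC RECONSTRUCTION
# Shared rows are standard literature values for mammalian neurons;
# cell-specific charge densities and mobility are synthetic values
# constructed to reproduce the documented qualitative electrostatics
# of each cell type (see vignette, section 'The cell presets').

eps_bilayer = 2                    # hydrophobic core
eps_extracellular = 81             # aqueous regions
eps_glycocalyx = 81
eps_cytoplasm = 81
glycocalyx_width_hg_cm = 2.5e-7    # 2.5 nm
bilayer_thickness_hb_cm = 7.5e-7   # 7.5 nm
mono_conc_extracellular_mol_cm3 = 1.54e-4   # 0.154 M saline
mono_conc_S1_mol_cm3 = 1.54e-4
div_conc_extracellular_mol_cm3 = 2.0e-6     # 0.002 M
div_conc_S1_mol_cm3 = 2.0e-6
mono_conc_cytoplasm_mol_cm3 = 1.54e-4
div_conc_cytoplasm_mol_cm3 = 4.0e-7         # 0.0004 M
temperature_K = 310
boltzmann_k_erg_K = 1.380649e-16
electron_charge_statC = 4.80320425e-10
viscosity_poise = 1                # 0.1 Pa s

rho_f_glycocalyx_statC_cm3 =      -4e+10    # synthetic
rho_f_cytoplasm_statC_cm3 =   -25000000     # synthetic
sigma_S1_statC_cm2 =  -1033.6145            # synthetic
sigma_S2_statC_cm2 =  -668.61338            # synthetic
sigma_S3_statC_cm2 =       -3000            # synthetic
electrophoretic_mobility_cm2_statV_s = -0.00032251188  # synthetic (zeta         -15 mV)
transmembrane_potential_mV =          35    # action state
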