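# Frozen default calibration of the reduced single-neuron
# energy-metabolism model. Units: mM, s, mV, mmHg.
# Conserved pool totals (mM)
pool_a_cyt: 2.5
pool_a_mit: 2.5
pool_n_cyt: 0.5
pool_n_mit: 1.0
pool_fad: 1.0
# Glucose transport (GLUT)
glut_vmax: 0.05
glut_km: 9.0
# Lumped glycolysis (upper ATP-investing + lower ATP/NADH-producing)
gly_vmax: 0.1
gly_km_glc: 0.1
gly_km_atp: 0.05
gly_km_adp: 0.3
gly_km_nad: 0.05
# Lactate dehydrogenase (reversible mass action)
ldh_k: 200.0
ldh_keq: 9000.0
# MCT2 lactate transport (H+-coupled carrier)
mct_vmax: 0.045
mct_km: 3.0
# Pyruvate oxidation + citric acid cycle (lumped, Ca-activated)
tca_vmax: 0.12
tca_km_pyr: 0.05
tca_km_nad: 0.1
tca_ca_act: 2.0
tca_ca_km: 2.0
# Malate-aspartate shuttle
mas_vmax: 0.06
mas_km_nadh: 0.002
mas_km_nad: 0.1
# Glycerol-3-phosphate shuttle
g3p_vmax: 0.02
g3p_km_nadh: 0.005
g3p_km_fad: 0.1
# Respiratory chain (NADH- and FADH2-fed proton pumping)
c1_vmax: 0.6
c1_km: 0.1
c2_vmax: 0.2
c2_km: 0.1
km_o2: 1.0
chain_psi_half: 150.0
chain_psi_slope: 18.0
# ATP synthase
syn_vmax: 1.2
syn_km_adp: 0.05
syn_pmf_half: 150.0
syn_pmf_slope: 25.0
# Adenine nucleotide translocator
ant_vmax: 1.2
ant_km: 0.3
ant_psi_half: 80.0
ant_psi_slope: 25.0
# Proton leak and membrane capacitance
leak_g: 0.01
leak_scale: 100.0
c_psi: 0.005
# pH gradient partition (fraction of dpsi carried as Z*dpH) and cytosolic pH
ph_frac: 0.2
ph_relax: 5.0
ph_cyt: 7.0
# Mitochondrial calcium (quasi-steady modulator; uM)
ca_max: 2.0
ca_psi_half: 130.0
ca_psi_slope: 25.0
ca_relax: 10.0
# Proton stoichiometries
h_per_nadh: 10.0
h_per_fadh2: 6.0
h_per_atp_syn: 3.0
# Energy demand (ATPase)
atpase_km: 0.25
# Calibration: maximal steady ATP turnover on 5 mM glucose / 0 lactate
t_max_atp: 0.480658
# Named demand levels as fractions of t_max_atp
demand_frac_low: 0.10
demand_frac_intermediate: 0.45
demand_frac_high: 0.85
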