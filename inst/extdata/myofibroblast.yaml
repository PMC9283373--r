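T_K: 310.0
dmu_over_kBT: 1.0
sigma_max: 240.0
eps_ss: 0.354
eta_max: 0.75
rho0: 3000000.0
mu_C: 1.67
m_C: 5.0
kappa_C: 35.0
mu_N: 3.3
m_N: 20.0
kappa_N: 35.0
b0_over_R0: 0.05
RN_over_R0: 0.453748185831812
H0: 0.032
Omega_log10_um3: -7.1
kappa_bar: 100000.0
Jc: 0.6
mu_u: 0.0
pi_NL: 1.0
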