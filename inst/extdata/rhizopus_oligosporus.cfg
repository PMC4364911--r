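# Reproductive aerial hypha of Rhizopus oligosporus
# Calibrated parameter set; dm / h / g unit system, units in the key names.
name = rhizopus_oligosporus
A_dm2 = 1e-8
D_dm2_h = 2.48e-4
kc_g_h = 2e-8
KC_g_dm3 = 400
kp_g_dm3_h = 1000
KP_g_dm3 = 10
m_g_g_h = 1.8e-3
omega0_g_dm3 = 5
v_dm_h = 0.026
YL_dm_g = 1e6
Yphi_g_g = 0.5
dx_dm = 1e-4
NV_tanks = 30
rhoX_g_dm3 = 100
psi_dm_h = 0.05
source_mode = constant
n0_tanks = 3
t_end_h = 24
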