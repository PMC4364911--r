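# Tall conidiophore of Aspergillus giganteus
name = aspergillus_giganteus
A_dm2 = 1.6e-7
D_dm2_h = 2.48e-4
kc_g_h = 3.2e-7
KC_g_dm3 = 1400
kp_g_dm3_h = 65
KP_g_dm3 = 10
m_g_g_h = 1.8e-2
omega0_g_dm3 = 60
v_dm_h = 0.0236
YL_dm_g = 6.25e4
Yphi_g_g = 0.5
dx_dm = 4e-4
NV_tanks = 40
rhoX_g_dm3 = 100
psi_dm_h = 0.007
source_mode = constant
n0_tanks = 3
t_end_h = 21
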