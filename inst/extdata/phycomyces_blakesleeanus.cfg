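# Sporangiophore of Phycomyces blakesleeanus, final growth stage.
# Simulation zero corresponds to 20 h of the original cultivation; the
# finite source tank depletes over the roughly 110 h horizon.
name = phycomyces_blakesleeanus
A_dm2 = 2.25e-6
A0_dm2 = 0.025
D_dm2_h = 2.48e-4
kc_g_h = 4.5e-5
KC_g_dm3 = 100
kp_g_dm3_h = 1000
KP_g_dm3 = 10
m_g_g_h = 1.8e-2
omega0_g_dm3 = 40
v_dm_h = 0.15
YL_dm_g = 4.44e3
Yphi_g_g = 0.5
dx_dm = 1.5e-3
NV_tanks = 5
rhoX_g_dm3 = 100
psi_dm_h = 0.75
source_mode = depleting
n0_tanks = 150
t_end_h = 110
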