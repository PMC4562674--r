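# fibrosim parameter set (g, cm, day units)
D_M: 8.6400000000000001e-07  # [cm^2/day] table; dispersion of macrophages
D_P: 0.17280000000000001  # [cm^2/day] table; diffusion of MCP-1
D_G: 0.086400000000000005  # [cm^2/day] table; diffusion of PDGF
D_Q: 0.043200000000000002  # [cm^2/day] table; diffusion of MMP
D_Qr: 0.043200000000000002  # [cm^2/day] table; diffusion of TIMP
D_Tbeta: 0.043200000000000002  # [cm^2/day] table; diffusion of TGF-beta
D_Talpha: 0.0129  # [cm^2/day] table; diffusion of TNF-alpha
D_f: 1.4699999999999999e-06  # [cm^2/day] table; dispersion of fibroblasts
D_m: 1.47e-05  # [cm^2/day] table; dispersion of myofibroblasts
D_I13: 0.010800000000000001  # [cm^2/day] table; diffusion of IL-13
chi_P: 10  # [cm^5/(g day)] table; chemotactic sensitivity of M1 to MCP-1
lambda_MT: 0.0050000000000000001  # [1/day] table; M2 -> M1 repolarization by TNF-alpha
lambda_M1: 0.00016984993987558843  # [1/day] calibrated; M1 -> M2 polarization
lambda_E0: 0.25  # [1/day] estimated; AEC activation rate in the damaged region
lambda_1: 0.001  # [g/(cm^3 day)] estimated; fibrocyte-mediated AEC repair amplitude
lambda_EM: 0.00165  # [1/day] estimated; EMT rate of activated AEC
lambda_TbetaM: 0.014999999999999999  # [1/day] table; TGF-beta production by M2 macrophages
lambda_Tbetaf: 0.0074999999999999997  # [1/day] estimated; TGF-beta production by fibroblasts
lambda_GM: 2.4000000000000001e-05  # [1/day] table; PDGF production by M2 macrophages
lambda_QM: 0.00029999999999999997  # [1/day] table; MMP production by M2 macrophages
lambda_QrM: 6.0000000000000002e-05  # [1/day] table; TIMP production by M2 macrophages
lambda_PE: 1e-08  # [1/day] table; MCP-1 production by activated AEC
lambda_rhof: 0.0030000000000000001  # [1/day] table; ECM production by fibroblasts
lambda_rhom: 0.0060000000000000001  # [1/day] table; ECM production by myofibroblasts
lambda_rhoTbeta: 2  # [] table; TGF-beta enhancement of ECM production
lambda_Ef: 0.00011749235354700866  # [1/day] calibrated; fibroblast source from resting AEC (bFGF proxy)
lambda_fE: 0.00050000000000000001  # [1/day] estimated; fibroblast proliferation by TGF-beta/IL-13 + AEC
lambda_mfT: 0.12  # [1/day] table; fibroblast -> myofibroblast by TGF-beta
lambda_mfG: 0.12  # [1/day] table; fibroblast -> myofibroblast by PDGF
lambda_TalphaM: 1.3900000000000001e-05  # [1/day] table; TNF-alpha production by M1 macrophages
lambda_TalphaE: 1.7546808411607302e-06  # [1/day] calibrated; TNF-alpha production by epithelium
lambda_I13: 2.1199999999999999e-07  # [g/(cm^3 day)] table; IL-13 source (Th2 cells, lumped)
lambda_I13M: 0.00039800000000000002  # [1/day] table; IL-13 production by M2 macrophages
d_M1: 0.02  # [1/day] table; M1 macrophage death
d_M2: 0.014999999999999999  # [1/day] table; M2 macrophage death
d_E: 0.016500000000000001  # [1/day] table; activated AEC death
d_E0: 0.016500000000000001  # [1/day] table; resting AEC death
d_E0T: 0.00165  # [] table; TGF-beta enhancement of AEC apoptosis
delta: 0.001  # [] estimated; oxidative-stress apoptosis excess in the injury
d_rho: 0.0044778515772602645  # [1/day] calibrated; ECM degradation
d_P: 1.73  # [1/day] table; MCP-1 degradation
d_PM: 0.00020799999999999999  # [1/day] table; MCP-1 internalization by M1 macrophages
d_G: 3.8399999999999999  # [1/day] table; PDGF degradation
d_QQr: 498000000  # [cm^3/(g day)] table; MMP loss by binding to TIMP
d_QrQ: 1040000000  # [cm^3/(g day)] table; TIMP loss by binding to MMP
d_Q: 4.3200000000000003  # [1/day] table; MMP degradation
d_Qr: 21.600000000000001  # [1/day] table; TIMP degradation
d_rhoQ: 25900000  # [cm^3/(g day)] table; ECM degradation by MMP
d_Tbeta: 333  # [1/day] table; TGF-beta degradation
d_f: 0.0166  # [1/day] table; fibroblast death
d_m: 0.0166  # [1/day] table; myofibroblast death
d_Talpha: 55.450000000000003  # [1/day] table; TNF-alpha degradation
d_I13: 12.470000000000001  # [1/day] table; IL-13 degradation
A_E0: 0.013035526626207201  # [g/(cm^3 day)] calibrated; intrinsic AEC proliferation
K_G: 1.4999999999999999e-08  # [g/cm^3] table; PDGF saturation
K_Tbeta: 1e-10  # [g/cm^3] table; TGF-beta saturation
K_P: 5.0000000000000001e-09  # [g/cm^3] table; MCP-1 saturation
K_Talpha: 4.9999999999999998e-07  # [g/cm^3] table; TNF-alpha saturation
K_I13: 1.9999999999999999e-07  # [g/cm^3] table; IL-13 saturation
K_E: 0.10000000000000001  # [g/cm^3] estimated; AEC saturation
rho_0: 0.01  # [g/cm^3] table; ECM carrying density
rho_star: 0.0032599999999999999  # [g/cm^3] estimated; ECM density in health
E_star: 0.79900000000000004  # [g/cm^3] estimated; AEC density in health
f_star: 0.0047499999999999999  # [g/cm^3] estimated; fibroblast density in health
M_0: 5.0000000000000002e-05  # [g/cm^3] table; blood monocyte density (M1 source)
beta: 0.20000000000000001  # [1/day] table; M1 influx rate (post-homogenization volumetric form)
K_D: 0.01  # [g/cm^3] unvalued; saturation of the fibrocyte repair term
lambda_MTalpha: 0.0050000000000000001  # [1/day] unvalued; TNF-alpha consumption during M2 -> M1 switching
lambda_TbetaI13: 1  # [] unvalued; IL-13 enhancement amplitude of TGF-beta production
lambda_S: 1  # [] unvalued; scar density coefficient
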