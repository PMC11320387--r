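# Release of methane from a collapsed 50 nm microgel (times in units of
# tau0 = 1 nm^2 / D_w; the summary also reports ns via the Stokes radius).
molecule:
  symbol: Me
microgel:
  b_nm: 50
  delta_nm: 1
  phi_p0: 0.5
  R_over_b: 20
solver:
  scheme: implicit
  dt_tau0: 1.0e-4
  dt_growth: 0.002
  f_stop: 0.99
  outer_bc: absorbing
rho0_M: 0.01
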