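# Baseline corneal slice configuration (all values optional; these are the
# package defaults, spelled out for reference). Units in key names.
R_A_mm: 7.8
T_mm: 0.62
D_A_mm: 11.46
depth_mm: 1
N: 32
gamma: 20
K1_N_mm: 7.2
K2_N_mm: 0.0072
K3_N_mm: 0.504
p_kPa: 2
damage:
  Dmax: 0.99
  xi: 4
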