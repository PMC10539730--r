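# Benchtop (1 T) two-cryptophane mixture, with UFZ gradient keys.
# rf carrier midway between the two caged-xenon resonances.
larmor_mhz = 12.09
gamma_bar_mhz_t = 11.79
gamma_sign = -1
delta_a_ppm = 196
r1a_per_s = 0.1
r2a_per_s = 10
omega1_rad_s = 64.7
offset_ppm = 47
tsat_s = 3
f_1 = 0.037
kout_1_per_s = 50
delta_b_1_ppm = 52
f_2 = 0.025
kout_2_per_s = 100
delta_b_2_ppm = 42
d_m = 0.0043
gsat_mt_m = 21
gacq_mt_m = 84
n_positions = 512
noise_sigma = 0
off_scale = 1
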