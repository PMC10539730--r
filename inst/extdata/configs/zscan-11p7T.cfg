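# High-field (11.7 T) Z-spectrum scenario: single cryptophane, strong
# CW saturation (7 uT) for 1 s.
larmor_mhz = 138.36
gamma_bar_mhz_t = 11.79
gamma_sign = -1
delta_a_ppm = 196
r1a_per_s = 0.01
r2a_per_s = 50
omega1_rad_s = 521.4
offset_ppm = 52
tsat_s = 1
f_1 = 0.04
kout_1_per_s = 50
delta_b_1_ppm = 52
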