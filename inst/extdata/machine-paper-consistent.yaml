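# "paper-consistent" machine profile: the package defaults, spelled out.
energy_list: {from: 70, to: 230, by: 1}   # MeV
bk_a: 0.0022        # cm / MeV^p
bk_p: 1.77
sigma0: 0.3         # cm, spot sigma in air at isocentre
energy_spread: 0.01 # fractional sigma_E / E
t_spot_switch: 0.002    # s
t_el_switch_up: 0.6     # s
t_el_switch_down: 0.6   # s
mu_rate: 40             # MU/s
gantry_speed: 0.921895006402049    # deg/s = 360 / 390.5
mu_per_weight: 1
field_setup_time: 0     # s per static field
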