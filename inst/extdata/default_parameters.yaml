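# Packaged default parameterization of the autophagy-control model.
# Tuned so the drug-free model reproduces the reference behaviors
# (see verify_calibration()): stationary AV count ~37 under severe stress
# (C_En = C_Nu = 0.1), oscillations with envelope ~[20, 27] under moderate
# stress (0.6), low stationary count under replete conditions (1.0), and
# the expected direction of each drug's long-time effect.
timescale: 1.0
C_En: 0.6
C_Nu: 0.6
k1: 0.13715
k2: 0.04645
k3: 3.9173
k4: 0.097932500
delta: [0.0116, 0.0173, 0.0231, 0.0277, 0.0154, 0.0198]
b: [1, 1, 1, 1, 1, 1]
regulation:
  h12: {rb: 0.09757, rm: 7.92835, theta: 0.27517, "n": 5.35062}
  h13: {rb: 0.05, rm: 1.41205, theta: 0.62156, "n": 4.53206}
  h23: {rb: 0.05, rm: 2.78171, theta: 0.9469, "n": 3.64888}
  h21: {rb: 0.42504, rm: 6.34521, theta: 0.741, "n": 4.25263}
  h42: {rb: 0.002, rm: 1.0, theta: 0.3556, "n": 11.58174}
drugs:
  H1: {rb: 0.05, rm: 1.0, theta: 1.0, "n": 2.0}
  H2: {rb: 0.02, rm: 1.0, theta: 1.0, "n": 2.0}
  H3: {rb: 0.02, rm: 1.0, theta: 1.0, "n": 2.0}
  H4: {rb: 0.01, rm: 1.0, theta: 0.5, "n": 4.0}
  H5: {rb: 0.01, rm: 1.0, theta: 1.0, "n": 2.0}
  H6: {rb: 0.02, rm: 1.0, theta: 1.0, "n": 2.0}
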