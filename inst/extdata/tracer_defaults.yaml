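# Default tracer definitions used by the simulator.
#
# These are synthetic, documented stand-ins on the scale of published
# human values: a Feng-type multi-exponential bolus input
#   Cp(t) = (A1*t - A2 - A3) * exp(-l1*t) + A2 * exp(-l2*t) + A3 * exp(-l3*t)
# (t in minutes, amplitudes in kBq/mL, A1 in kBq/mL/min, rates in 1/min)
# and per-ROI two-tissue-compartment means (K1 mL/min/mL, k2..k4 1/min).
# Everything here is config-overridable at run time.
tracers:
  FDG:
    half_life_s: 6586.2        # F-18
    input_model: feng
    input_params: [851.1, 21.9, 20.8, 4.134, 0.0104, 0.119]
    kinetics:                  # rows = ROI 1..5: [K1, k2, k3, k4]
      - [0.102, 0.130, 0.062, 0.0068]
      - [0.140, 0.150, 0.080, 0.0070]
      - [0.080, 0.120, 0.045, 0.0060]
      - [0.054, 0.110, 0.030, 0.0050]
      - [0.160, 0.170, 0.095, 0.0080]
  FMZ:
    half_life_s: 1223.4        # C-11
    input_model: feng
    input_params: [600.0, 15.0, 25.0, 3.5, 0.012, 0.090]
    kinetics:
      - [0.360, 0.420, 0.055, 0.038]
      - [0.450, 0.400, 0.065, 0.040]
      - [0.300, 0.460, 0.045, 0.035]
      - [0.220, 0.480, 0.035, 0.030]
      - [0.520, 0.380, 0.075, 0.042]
  Acetate:
    half_life_s: 1223.4        # C-11
    input_model: feng
    input_params: [400.0, 25.0, 30.0, 2.8, 0.008, 0.060]
    kinetics:
      - [0.600, 0.900, 0.300, 0.014]
      - [0.750, 0.850, 0.360, 0.015]
      - [0.500, 0.950, 0.250, 0.012]
      - [0.380, 1.000, 0.200, 0.010]
      - [0.850, 0.800, 0.420, 0.016]
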