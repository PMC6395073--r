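# Gating kinetics of the seven voltage-gated currents, after Liu, Golowasch,
# Abbott & Marder (1998) J Neurosci 18:2309-2320 (lobster STG neurons).
# Steady states: x_inf(V) = 1 / (1 + exp((V - v_half) / k))   [mV]
# Time constants [ms], three functional forms:
#   sigmoid: offset + amplitude / (1 + exp((V + v_offset) / slope))
#   biexp:   offset + amplitude / (exp((V + v1)/k1) + exp((V + v2)/k2))
#   product: scale/(1 + exp((V + v1)/k1)) * (base + 1/(1 + exp((V + v2)/k2)))
# KCa activation is multiplied by Ca / (Ca + ca_half), Ca in uM.
# reversal: ion identity; numeric values live in the model parameters
# (Ca channels use the Nernst potential computed from intracellular Ca).
channels:
  Na:
    p: 3
    q: 1
    reversal: Na
    m_inf: {v_half: -25.5, k: -5.29}
    h_inf: {v_half: -48.9, k: 5.18}
    tau_m: {form: sigmoid, offset: 1.32, amplitude: -1.26, v_offset: 120.0, slope: -25.0}
    tau_h: {form: product, scale: 0.67, v1: 62.9, k1: -10.0, base: 1.5, v2: 34.9, k2: 3.6}
  CaT:
    p: 3
    q: 1
    reversal: nernst-calcium
    m_inf: {v_half: -27.1, k: -7.2}
    h_inf: {v_half: -32.1, k: 5.5}
    tau_m: {form: sigmoid, offset: 43.4, amplitude: -42.6, v_offset: 68.1, slope: -20.5}
    tau_h: {form: sigmoid, offset: 210.0, amplitude: -179.6, v_offset: 55.0, slope: -16.9}
  CaS:
    p: 3
    q: 1
    reversal: nernst-calcium
    m_inf: {v_half: -33.0, k: -8.1}
    h_inf: {v_half: -60.0, k: 6.2}
    tau_m: {form: biexp, offset: 2.8, amplitude: 14.0, v1: 27.0, k1: 10.0, v2: 70.0, k2: -13.0}
    tau_h: {form: biexp, offset: 120.0, amplitude: 300.0, v1: 55.0, k1: 9.0, v2: 65.0, k2: -16.0}
  A:
    p: 3
    q: 1
    reversal: K
    m_inf: {v_half: -27.2, k: -8.7}
    h_inf: {v_half: -56.9, k: 4.9}
    tau_m: {form: sigmoid, offset: 23.2, amplitude: -20.8, v_offset: 32.9, slope: -15.2}
    tau_h: {form: sigmoid, offset: 77.2, amplitude: -58.4, v_offset: 38.9, slope: -26.5}
  KCa:
    p: 4
    q: 0
    reversal: K
    m_inf: {v_half: -28.3, k: -12.6, ca_half: 3.0}
    tau_m: {form: sigmoid, offset: 180.6, amplitude: -150.2, v_offset: 46.0, slope: -22.7}
  Kd:
    p: 4
    q: 0
    reversal: K
    m_inf: {v_half: -12.3, k: -11.8}
    tau_m: {form: sigmoid, offset: 14.4, amplitude: -12.8, v_offset: 28.3, slope: -19.2}
  H:
    p: 1
    q: 0
    reversal: H
    m_inf: {v_half: -75.0, k: 5.5}
    tau_m: {form: biexp, offset: 0.0, amplitude: 2.0, v1: 169.7, k1: -11.6, v2: -26.7, k2: 14.3}
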