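{
  "label": "canonical",
  "a1": 2.05,
  "a2": 1.25,
  "a3": 0.2,
  "b": 1.5155757471,
  "poles": [1.0, 0.8, 0.25],
  "note": "Third-order linear ODE x''' + a1 x'' + a2 x' + a3 x = b u(t). All-real-pole system (1.0, 0.8, 0.25 s^-1): rise constants ~1 s, decay constant 4 s. Gain b scales the impulse response to unit peak; peak latency 3.375 s.",
  "version": 1
}
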