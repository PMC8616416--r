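# Human-dermis optical properties at the working wavelengths (1/mm, nm),
# with chlorin-e6 photosensitizer amplitudes for a 0.1% vol gel.
properties:
  405: {mu_a: 0.96, mu_s: 38, g: 0.8, n: 1.37}
  660: {mu_a: 0.15, mu_s: 14, g: 0.8, n: 1.37}
  760: {mu_a: 0.13, mu_s: 12, g: 0.8, n: 1.37}
ps:
  mu_a_ps: {blue: 0.1, red: 0.02}
  M0: {blue: 0.02, red: 0.004}
phi: {blue: 1, red: 1}
m: 2.76
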