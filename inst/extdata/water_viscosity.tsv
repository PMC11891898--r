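# Shear viscosity of water (mPa s) as a function of temperature:
# TIP3P model values from periodic-perturbation simulations and the
# experimental liquid. Simulation-derived input data shipped with the
# package; not recomputed.
T_K	tip3p	expt
273.15	0.445	1.793
278.15	0.412	1.518
283.15	0.388	1.307
288.15	0.355	1.137
293.15	0.337	1.002
298.15	0.319	0.890
303.15	0.299	0.798
308.15	0.283	0.719
313.15	0.273	0.653
318.15	0.254	0.596
323.15	0.244	0.547
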