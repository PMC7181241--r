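# Equilibrium mole-fraction solubility of emtricitabine in PEG-400 + water
# mixtures, T = 298.2-318.2 K, p = 0.1 MPa; values to 3 significant figures.
# solute: emtricitabine, 247.24
# cosolvent: PEG-400, 400
# antisolvent: water, 18.07
m,298.2,303.2,308.2,313.2,318.2
0.0,7.95e-3,8.74e-3,9.53e-3,1.05e-2,1.15e-2
0.1,1.01e-2,1.11e-2,1.19e-2,1.30e-2,1.44e-2
0.2,1.31e-2,1.41e-2,1.54e-2,1.70e-2,1.84e-2
0.3,1.70e-2,1.88e-2,2.02e-2,2.22e-2,2.39e-2
0.4,2.27e-2,2.48e-2,2.68e-2,2.92e-2,3.20e-2
0.5,2.95e-2,3.21e-2,3.47e-2,3.78e-2,4.12e-2
0.6,3.81e-2,4.17e-2,4.50e-2,4.84e-2,5.30e-2
0.7,4.95e-2,5.41e-2,5.80e-2,6.26e-2,6.82e-2
0.8,6.33e-2,6.90e-2,7.43e-2,7.98e-2,8.68e-2
0.9,8.28e-2,9.01e-2,9.69e-2,1.03e-1,1.11e-1
1.0,1.06e-1,1.16e-1,1.25e-1,1.33e-1,1.45e-1
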