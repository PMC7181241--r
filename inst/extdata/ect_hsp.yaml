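# Total Hansen solubility parameters, MPa^0.5
solute: 25.90
cosolvent: 18.90
antisolvent: 47.80
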