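# Fusion properties of emtricitabine from thermal analysis
# (dh_fus in kJ/mol; converted to J/mol on load)
name: emtricitabine
t_fus: 427.80
dh_fus: 32.37
dcp: 75.66
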