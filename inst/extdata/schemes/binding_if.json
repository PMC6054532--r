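{"name":"binding_if","species":[{"name":"E","role":"free_enzyme_state","state_tag":null},{"name":"I","role":"free_ligand","state_tag":null},{"name":"E.I","role":"complex","state_tag":null},{"name":"E_star.I","role":"complex","state_tag":"starred"}],"reactions":[{"reactants":["E","I"],"products":["E.I"],"forward_name":"k2","reverse_name":"k_m2","forward_order":2},{"reactants":["E.I"],"products":["E_star.I"],"forward_name":"k3","reverse_name":"k_m3","forward_order":1}],"constants":{"values":[],"errors":[]}}
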