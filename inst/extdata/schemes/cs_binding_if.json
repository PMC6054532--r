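{"name":"cs_binding_if","species":[{"name":"E_in","role":"free_enzyme_state","state_tag":"DFG_in"},{"name":"E_out","role":"free_enzyme_state","state_tag":"DFG_out"},{"name":"I","role":"free_ligand","state_tag":null},{"name":"E_out.I","role":"complex","state_tag":"DFG_out"},{"name":"E_out_star.I","role":"complex","state_tag":"DFG_out_star"}],"reactions":[{"reactants":["E_in"],"products":["E_out"],"forward_name":"k1","reverse_name":"k_m1","forward_order":1},{"reactants":["E_out","I"],"products":["E_out.I"],"forward_name":"k2","reverse_name":"k_m2","forward_order":2},{"reactants":["E_out.I"],"products":["E_out_star.I"],"forward_name":"k3","reverse_name":"k_m3","forward_order":1}],"constants":{"values":[],"errors":[]}}
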