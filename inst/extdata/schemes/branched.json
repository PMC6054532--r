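{"name":"branched","species":[{"name":"E_out","role":"free_enzyme_state","state_tag":"DFG_out"},{"name":"E_in","role":"free_enzyme_state","state_tag":"DFG_in"},{"name":"I","role":"free_ligand","state_tag":null},{"name":"E_in.I","role":"complex","state_tag":"DFG_in"},{"name":"E_in_star.I","role":"complex","state_tag":"DFG_in_star"},{"name":"E_out.I","role":"complex","state_tag":"DFG_out"}],"reactions":[{"reactants":["E_out"],"products":["E_in"],"forward_name":"k1","reverse_name":"k_m1","forward_order":1},{"reactants":["E_in","I"],"products":["E_in.I"],"forward_name":"k2","reverse_name":"k_m2","forward_order":2},{"reactants":["E_in.I"],"products":["E_in_star.I"],"forward_name":"k3","reverse_name":"k_m3","forward_order":1},{"reactants":["E_out","I"],"products":["E_out.I"],"forward_name":"k4","reverse_name":"k_m4","forward_order":2}],"constants":{"values":[],"errors":[]}}
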