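cohort	n_nodes	n_edges	reported_edge_density	reported_average_node_degree
lean_ghana	76	1503	0.53	39.55
obese_ghana	70	1226	0.51	35.03
lean_us	77	1237	0.42	32.13
obese_us	83	846	0.25	20.39
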