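compartment	nerve	d1	d2	d3	md	fa	axial_radial_ratio	n_slices
fascicle	1	0.77	0.40	0.37	0.51	0.41	1.99	12
fascicle	2	0.69	0.35	0.31	0.45	0.44	2.22	13
fascicle	3	0.90	0.45	0.41	0.59	0.43	2.15	8
fascicle	4	0.89	0.50	0.46	0.62	0.38	1.89	11
fascicle	5	0.78	0.34	0.29	0.47	0.52	2.51	12
fascicle	mean	0.81	0.41	0.37	0.51	0.44	2.15	56
epineurium	1	0.03	0.03	0.02	0.03	0.13	1.20	12
epineurium	2	0.04	0.03	0.03	0.03	0.14	1.20	13
epineurium	3	0.04	0.03	0.03	0.03	0.14	1.12	8
epineurium	4	0.03	0.03	0.03	0.03	0.11	1.12	11
epineurium	5	0.03	0.03	0.03	0.03	0.12	1.12	12
epineurium	mean	0.03	0.03	0.03	0.03	0.13	1.15	56
perineurium	1	1.06	0.74	0.55	0.78	0.33	1.65	12
perineurium	2	1.12	0.92	0.53	0.83	0.32	1.54	13
perineurium	3	1.10	0.79	0.54	0.82	0.34	1.70	8
perineurium	4	1.10	0.73	0.66	0.84	0.27	1.54	11
perineurium	5	0.96	0.57	0.41	0.64	0.40	1.97	12
perineurium	mean	1.07	0.75	0.53	0.78	0.33	1.68	56
nerve	mean	0.46	0.30	0.28	0.34	0.28	NA	56
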