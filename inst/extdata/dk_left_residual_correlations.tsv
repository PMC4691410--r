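region	r_thickness_adjacent	p_thickness_adjacent	sig_thickness_adjacent	r_thickness_cortical	p_thickness_cortical	sig_thickness_cortical	r_cortical_adjacent	p_cortical_adjacent	sig_cortical_adjacent
caudal_anterior_cingulate	-0.184	0.0144	FALSE	-0.106	0.162	FALSE	0.282	0.000139	TRUE
caudal_middle_frontal	-0.274	0.00023	TRUE	-0.27	0.000274	TRUE	0.556	8.88e-16	TRUE
cuneus	0.159	0.0347	FALSE	0.102	0.177	FALSE	0.495	2.41e-12	TRUE
entorhinal	-0.024	0.747	FALSE	0.007	0.926	FALSE	0.16	0.0335	FALSE
frontal_pole	0.202	0.00692	FALSE	-0.055	0.469	FALSE	0.51	4.13e-13	TRUE
fusiform	-0.19	0.0113	FALSE	-0.146	0.0527	FALSE	0.44	8.67e-10	TRUE
inferior_parietal	-0.333	6.11e-06	TRUE	-0.32	1.40e-05	TRUE	0.547	3.33e-15	TRUE
inferior_temporal	-0.184	0.0141	FALSE	-0.416	8.41e-09	TRUE	0.369	4.24e-07	TRUE
insula	0.05	0.512	FALSE	-0.063	0.402	FALSE	0.61	0	TRUE
isthmus_cingulate	0	0.998	FALSE	-0.007	0.924	FALSE	0.313	2.22e-05	TRUE
lateral_occipital	-0.139	0.0645	FALSE	-0.208	0.00552	FALSE	0.414	1.02e-08	TRUE
lateral_orbitofrontal	0.028	0.709	FALSE	-0.049	0.515	FALSE	0.419	6.19e-09	TRUE
lingual	0.061	0.419	FALSE	0.131	0.081	FALSE	0.245	0.00103	TRUE
medial_orbitofrontal	0.172	0.022	FALSE	0.136	0.0721	FALSE	0.465	7.33e-11	TRUE
middle_temporal	-0.239	0.00133	FALSE	-0.474	2.70e-11	TRUE	0.489	5.14e-12	TRUE
paracentral	0.097	0.199	FALSE	-0.038	0.615	FALSE	0.458	1.44e-10	TRUE
parahippocampal	0.154	0.0405	FALSE	0.049	0.52	FALSE	0.439	1.01e-09	TRUE
pars_opercularis	-0.252	0.000717	TRUE	-0.316	1.81e-05	TRUE	0.518	1.50e-13	TRUE
pars_orbitalis	-0.21	0.00496	FALSE	-0.237	0.00151	FALSE	0.382	1.49e-07	TRUE
pars_triangularis	-0.237	0.0015	FALSE	-0.264	0.000385	TRUE	0.572	0	TRUE
pericalcarine	0.154	0.0402	FALSE	0.142	0.0601	FALSE	0.74	0	TRUE
postcentral	0.068	0.372	FALSE	-0.194	0.0098	FALSE	0.545	4.00e-15	TRUE
posterior_cingulate	-0.076	0.312	FALSE	-0.125	0.0983	FALSE	0.312	2.42e-05	TRUE
precentral	-0.024	0.748	FALSE	-0.13	0.0843	FALSE	0.53	3.20e-14	TRUE
precuneus	0.217	0.00371	FALSE	0.005	0.943	FALSE	0.297	6.11e-05	TRUE
rostral_anterior_cingulate	-0.209	0.00528	FALSE	-0.195	0.00912	FALSE	0.317	1.73e-05	TRUE
rostral_middle_frontal	-0.318	1.66e-05	TRUE	-0.257	0.000562	TRUE	0.592	0	TRUE
superior_frontal	-0.28	0.000164	TRUE	-0.144	0.0566	FALSE	0.553	1.33e-15	TRUE
superior_parietal	0.123	0.102	FALSE	0.058	0.439	FALSE	0.566	2.22e-16	TRUE
superior_temporal	-0.239	0.00138	FALSE	-0.316	1.83e-05	TRUE	0.549	2.44e-15	TRUE
supramarginal	-0.374	3.02e-07	TRUE	-0.387	1.01e-07	TRUE	0.607	0	TRUE
temporal_pole	0.102	0.178	FALSE	0.094	0.214	FALSE	0.177	0.0185	FALSE
transverse_temporal	0.249	0.000851	TRUE	-0.08	0.287	FALSE	0.603	0	TRUE
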