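region	thickness_slope	thickness_intercept	adjacent_mwf_slope	adjacent_mwf_intercept	cortical_mwf_slope	cortical_mwf_intercept
caudal_anterior_cingulate	-0.179	4.566	0.029	-0.07	0.016	-0.058
caudal_middle_frontal	-0.23	4.452	0.022	-0.035	0.017	-0.056
cuneus	-0.267	4.096	0.014	0.005	0.013	-0.031
entorhinal	0	2.86	0.01	0.025	0.015	-0.057
frontal_pole	-0.09	3.963	0.019	-0.051	0.016	-0.057
fusiform	-0.22	4.399	0.014	0.011	0.012	-0.024
inferior_parietal	-0.142	3.609	0.011	0.029	0.012	-0.021
inferior_temporal	-0.303	4.902	0.014	0.02	0.019	-0.063
insula	-0.145	4.5	0.011	0.031	0.014	-0.051
isthmus_cingulate	-0.297	5.172	0.016	0.019	0.009	-0.011
lateral_occipital	-0.196	3.687	0.01	0.034	0.012	-0.008
lateral_orbitofrontal	-0.092	3.908	0.029	-0.087	0.02	-0.086
lingual	-0.275	4.286	0.014	0.01	0.008	0.003
medial_orbitofrontal	-0.331	5.443	0.024	-0.064	0.02	-0.091
middle_temporal	-0.264	4.514	0.015	0.016	0.014	-0.036
paracentral	-0.141	3.605	0.017	-0.001	0.01	-0.019
parahippocampal	-0.061	3.09	0.016	-0.025	0.01	-0.022
pars_opercularis	-0.23	4.488	0.024	-0.037	0.015	-0.049
pars_orbitalis	-0.38	5.952	0.015	-0.001	0.016	-0.06
pars_triangularis	-0.276	4.662	0.026	-0.06	0.016	-0.053
pericalcarine	-0.199	3.303	0.016	-0.001	0.01	0.001
postcentral	-0.145	3.26	0.013	0.023	0.011	-0.011
posterior_cingulate	-0.098	3.807	0.023	-0.035	0.013	-0.036
precentral	-0.099	3.188	0.018	-0.004	0.013	-0.027
precuneus	-0.137	3.748	0.021	-0.027	0.012	-0.034
rostral_anterior_cingulate	-0.494	7.172	0.023	-0.029	0.015	-0.055
rostral_middle_frontal	-0.368	5.527	0.03	-0.098	0.019	-0.07
superior_frontal	-0.259	5.21	0.028	-0.083	0.015	-0.056
superior_parietal	-0.071	2.921	0.016	-0.009	0.013	-0.032
superior_temporal	-0.035	2.961	0.017	-0.002	0.012	-0.029
supramarginal	-0.19	4.026	0.015	0.014	0.011	-0.017
temporal_pole	0.059	2.846	0.004	0.065	0.014	-0.055
transverse_temporal	-0.108	3.326	0.018	-0.011	0.011	-0.011
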