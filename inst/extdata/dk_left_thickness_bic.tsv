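region	bic_logarithmic	bic_quadratic	bic_linear	flag_logarithmic	flag_quadratic	flag_linear
caudal_anterior_cingulate	164.18	168.59	163.46	TRUE	FALSE	TRUE
caudal_middle_frontal	98.71	103.54	100.95	TRUE	FALSE	FALSE
cuneus	45.12	49.44	54.83	TRUE	FALSE	FALSE
entorhinal	227.61	230.47	227.45	TRUE	FALSE	TRUE
frontal_pole	378.37	383	378.11	TRUE	FALSE	TRUE
fusiform	0.59	6.02	7.93	TRUE	FALSE	FALSE
inferior_parietal	51.05	52.96	52.85	TRUE	FALSE	FALSE
inferior_temporal	81.56	84.78	86.97	TRUE	FALSE	FALSE
insula	-29.7	-25.65	-30.7	TRUE	FALSE	TRUE
isthmus_cingulate	82.17	88.65	85.32	TRUE	FALSE	FALSE
lateral_occipital	-30.93	-36.74	-20.85	TRUE	TRUE	FALSE
lateral_orbitofrontal	65.43	66.58	63.72	TRUE	FALSE	TRUE
lingual	-6.86	-4.95	3.41	TRUE	FALSE	FALSE
medial_orbitofrontal	123.13	130.4	127.57	TRUE	FALSE	FALSE
middle_temporal	128.23	127.51	134.35	TRUE	TRUE	FALSE
paracentral	51.95	56.31	51.19	TRUE	FALSE	TRUE
parahippocampal	208.39	213.66	208.55	TRUE	FALSE	FALSE
pars_opercularis	80.85	86.17	83.89	TRUE	FALSE	FALSE
pars_orbitalis	224.75	229.88	225.04	TRUE	FALSE	FALSE
pars_triangularis	146.71	152.04	148.06	TRUE	FALSE	FALSE
pericalcarine	19.2	18.65	26.44	TRUE	TRUE	FALSE
postcentral	-9.1	-5.43	-7.11	TRUE	FALSE	FALSE
posterior_cingulate	26.44	28.68	24.48	TRUE	FALSE	TRUE
precentral	-64.76	-60.05	-64.5	TRUE	FALSE	FALSE
precuneus	-28.32	-26.58	-31.35	TRUE	FALSE	TRUE
rostral_anterior_cingulate	81.79	85.94	82.96	TRUE	FALSE	FALSE
rostral_middle_frontal	106.37	110.89	107.2	TRUE	FALSE	FALSE
superior_frontal	58.92	61.61	56.44	TRUE	FALSE	TRUE
superior_parietal	-57.97	-53.28	-57.94	TRUE	FALSE	FALSE
superior_temporal	32.07	36.93	32	TRUE	FALSE	TRUE
supramarginal	59.84	62	62.73	TRUE	FALSE	FALSE
temporal_pole	305.64	310.5	305.48	TRUE	FALSE	TRUE
transverse_temporal	138.96	143.86	138.72	TRUE	FALSE	TRUE
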