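isolate	compartment	genome_size_mb	scaffolds	gc	genes	coding	functional_prediction	kegg	similarity
GM25	rhizosphere	6.37	186	61	5836	90.3	81.2	28.1	99.5
GM48	rhizosphere	6.46	272	59	5977	87.7	81.1	29.1	99.6
GM49	rhizosphere	6.60	370	60	6340	88.1	80.6	28.3	99.6
GM74	rhizosphere	6.12	219	60	5649	88.2	81.4	29.8	99.6
GM16	endosphere	6.56	155	59	5981	88.6	79.6	26.9	98.9
GM18	endosphere	6.31	178	60	5797	89.2	80.5	28.8	99.3
GM21	endosphere	6.62	258	58	6154	88.0	79.1	27.9	99.4
GM24	endosphere	6.54	476	59	5974	88.8	79.3	27.0	99.3
GM30	endosphere	6.15	215	60	5696	88.3	79.6	26.9	99.4
GM33	endosphere	6.74	245	60	6177	88.3	82.0	28.6	99.3
GM41	endosphere	6.63	230	59	6150	88.6	80.9	28.6	99.4
GM50	endosphere	6.70	202	59	6151	88.1	79.9	27.5	99.2
GM55	endosphere	6.50	217	60	6068	87.9	81.1	28.7	99.5
GM60	endosphere	6.44	230	60	5991	88.2	80.9	28.5	99.6
GM67	endosphere	6.52	254	60	6086	88.4	79.3	27.8	99.6
GM78	endosphere	7.30	291	60	6804	88.8	81.0	27.7	99.6
GM79	endosphere	6.72	166	59	6146	87.6	79.7	28.0	99.1
GM80	endosphere	6.81	368	59	6334	88.2	77.2	25.8	99.4
GM102	endosphere	6.67	207	59	6126	88.1	79.8	27.9	99.1
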