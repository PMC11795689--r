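res	E_helix	P1_helix	P2_helix	B1_helix	B2_helix	B3_helix	E_sheet	P1_sheet	P2_sheet	B1_sheet	B2_sheet	B3_sheet	E_other	P1_other	P2_other	B1_other	B2_other	B3_other
A	-0.052	0.4	0.17	0.283	0.383	0.42	-0.123	0.33	0.1	0.212	0.312	0.35	-0.102	0.35	0.12	0.233	0.332	0.37
R	0.208	-0.245	-0.015	-1.2	-1.027	-0.465	0.202	-0.251	-0.021	-1.2	-1.033	-0.471	0.21	-0.242	-0.012	-1.2	-1.025	-0.462
N	0.372	-0.081	0.149	-0.598	-0.363	-0.101	0.398	-0.055	0.175	-0.572	-0.337	-0.075	0.411	-0.041	0.189	-0.559	-0.324	-0.061
D	0.322	-0.13	0.1	-1.148	-0.913	-0.35	0.266	-0.187	0.043	-1.2	-0.969	-0.407	0.321	-0.131	0.099	-1.149	-0.914	-0.351
C	-0.239	0.214	-0.016	0.297	0.352	0.234	-0.18	0.273	0.043	0.356	0.411	0.293	-0.203	0.25	0.02	0.333	0.388	0.27
Q	0.424	-0.028	0.202	-0.546	-0.311	-0.048	0.423	-0.029	0.201	-0.547	-0.312	-0.049	0.411	-0.041	0.189	-0.559	-0.324	-0.061
E	0.382	-0.07	0.16	-1.088	-0.853	-0.29	0.246	-0.207	0.023	-1.2	-0.989	-0.427	0.321	-0.131	0.099	-1.149	-0.914	-0.351
G	0.158	0.386	0.38	-0.131	0.104	0.141	0.179	0.408	0.402	-0.109	0.126	0.163	0.209	0.438	0.432	-0.079	0.156	0.193
H	0.444	-0.008	0.222	-1.026	-0.791	-0.228	0.429	-0.024	0.206	-1.041	-0.806	-0.244	0.444	-0.008	0.222	-1.026	-0.791	-0.228
I	-0.483	-0.03	-0.26	0.487	0.252	-0.01	-0.42	0.032	-0.198	0.549	0.314	0.052	-0.492	-0.04	-0.27	0.478	0.243	-0.02
L	-0.39	0.063	-0.167	0.525	0.345	0.083	-0.379	0.074	-0.156	0.536	0.356	0.094	-0.415	0.038	-0.192	0.5	0.32	0.058
K	0.296	-0.157	0.073	-1.174	-0.939	-0.377	0.245	-0.207	0.023	-1.2	-0.99	-0.427	0.277	-0.176	0.054	-1.193	-0.958	-0.396
M	-0.082	0.37	0.14	0.32	0.375	0.39	-0.13	0.322	0.092	0.272	0.327	0.342	-0.136	0.316	0.086	0.266	0.321	0.336
F	-0.288	0.164	-0.066	0.404	0.369	0.184	-0.258	0.194	-0.036	0.434	0.399	0.214	-0.304	0.149	-0.081	0.389	0.354	0.169
P	0.291	0.253	0.258	-0.264	-0.029	0.008	0.289	0.251	0.256	-0.267	-0.032	0.006	0.343	0.305	0.31	-0.213	0.022	0.06
S	0.271	0.321	0.416	-0.196	0.039	0.166	0.269	0.319	0.414	-0.199	0.036	0.164	0.299	0.349	0.444	-0.169	0.066	0.194
T	0.267	0.339	0.434	-0.178	0.057	0.184	0.311	0.383	0.478	-0.135	0.1	0.228	0.288	0.36	0.455	-0.158	0.077	0.205
W	0.23	0.437	0.352	-0.08	0.065	0.102	0.264	0.472	0.387	-0.046	0.099	0.137	0.22	0.428	0.342	-0.09	0.055	0.093
Y	0.317	0.256	0.351	-0.262	-0.027	0.101	0.411	0.349	0.444	-0.168	0.067	0.194	0.354	0.293	0.388	-0.224	0.011	0.138
V	-0.452	0.001	-0.229	0.518	0.283	0.021	-0.375	0.077	-0.153	0.595	0.36	0.097	-0.459	-0.007	-0.237	0.511	0.276	0.013
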