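property	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT
Base stacking	-0.146	0.723	-0.327	-0.433	0.269	-1.272	0.031	0.322	-1.346	-0.097	-0.901	-0.473	0.377	-0.095	1.102	-0.111
Protein induced deformability	-1.621	0.124	-0.321	-0.191	0.516	-0.107	-0.491	1.214	-0.5	0.81	2.736	-0.349	-0.67	1.858	0.227	-0.814
B-DNA twist	-0.885	-1.063	-0.272	0.227	-2.144	-1.886	-1.913	-0.466	0.515	-0.464	1.936	-1.292	0.02	-0.62	0.246	0.104
Dinucleotide GC Content	-0.417	-0.4	-1.525	0.751	-0.412	-0.864	1.619	0.732	-2.551	-0.594	1.59	0.887	-0.372	-0.694	-0.593	-0.353
A-philicity	-0.643	-0.193	-0.258	0.761	0.293	1.83	0.625	1.549	0.513	-0.321	-0.905	-0.948	1.232	0.327	0.433	-1.406
Propeller twist	0.764	-1.197	1.274	0.135	0.597	-0.223	0.795	0.13	0.915	1.814	1.537	-0.46	0.074	-0.042	-2.28	-0.53
Duplex stability (free energy)	-0.474	1.855	-0.215	-1.166	-0.237	0.257	-0.32	-0.901	-0.856	0.282	1.082	0.59	0.006	-1.246	0.654	2.389
Duplex stability (disrupt energy)	-0.166	1.087	-1.489	0.546	-1.576	0.28	0.407	-0.831	-1.34	0.982	1.336	-1.298	-0.196	0.07	0.487	0.489
DNA denaturation	0.139	0.033	-0.281	-0.645	-1.378	1.123	-0.544	0.102	-0.825	1.085	-0.301	-0.252	-0.37	-0.867	0.6	-2.289
Bending stiffness	1.849	0.811	0.397	-0.331	-0.493	-0.185	-0.947	-0.087	-1.514	1.157	-0.037	1.121	-1.827	-1.547	0.42	-1.075
Protein DNA twist	0.303	0.55	-1.096	-0.844	0.207	-0.414	0.25	-0.656	-1.181	-0.29	0.289	1.43	-0.5	0.877	0.418	-0.466
Stabilising energy of Z-DNA	-2.328	-0.831	-1.032	-1.055	0.026	0.159	0.167	2.896	-1.94	-0.827	0.653	1.123	0.881	-0.464	1.817	0.324
Aida_BA_transition	-0.942	-0.155	1.07	0.029	-0.384	-0.868	-0.147	0.68	-0.486	-1.007	1.98	-1.263	0.79	1.274	-0.561	-0.804
Breslauer_dG	0.038	-0.376	-0.982	0.225	-0.097	1.06	-0.103	0.75	2.106	-0.026	-0.654	-0.284	-0.311	0.727	1.236	-0.483
Breslauer_dH	-0.165	1.226	0.472	-0.777	-0.35	0.615	0.558	-0.289	-0.667	-0.18	1.426	-0.835	0.059	-0.936	0.282	0.072
Breslauer_dS	0.706	-0.787	1.554	-0.678	0.252	-0.73	-1.589	-0.168	0.169	0.222	0.675	-0.98	-0.338	1.715	0.785	-0.365
Electron_interaction	0.731	0.746	0.45	0.427	-0.756	-0.009	1.271	-0.77	0.522	0.019	-0.585	1.093	0.512	-0.808	-1.199	-1.679
Hartman_trans_free_energy	-0.94	0.166	0.818	-1.22	-1.379	-1.798	-0.059	-0.493	-1.43	-0.216	0.278	-1.45	-0.807	0.162	-0.071	0.29
Helix-Coil_transition	0.045	-1.531	-0.306	-0.005	-0.089	1.069	0.239	1.35	-0.91	0.44	0.164	-0.472	-3.656	-1.309	-0.605	-0.513
Ivanov_BA_transition	0.862	-0.598	0.162	0.921	-0.979	-1.156	-1.705	1.813	0.213	0.465	1.764	-0.005	-0.556	1.204	0.02	-0.557
Lisser_BZ_transition	1.511	1.108	0.521	0.139	-1.419	-0.528	1.652	-1.053	1.224	0.837	1.467	1.011	-1.025	0.749	-1.733	1.747
Polar_interaction	0.077	0.726	0.797	0.742	0.482	1.527	-0.36	0.628	-0.942	-0.39	0.54	0.417	-0.206	-0.359	-0.309	1.151
SantaLucia_dG	-0.202	-0.009	-0.637	-0.563	-0.199	0.191	-0.785	1.828	1.377	-0.532	-0.512	0.021	-0.388	-0.825	-1.243	-0.167
SantaLucia_dH	1.931	1.244	-0.731	0.24	-1.024	2.008	1.631	1.459	-0.093	-0.335	0.736	0.597	0.117	-0.847	0.101	2.535
SantaLucia_dS	-0.513	-0.857	0.411	0.559	-0.897	0.561	0.955	-0.213	-0.295	1.457	-0.196	0.631	-0.619	-0.447	1.759	-1.179
Sarai_flexibility	0.147	-0.703	1.626	0.242	0.251	-0.463	0.191	1.858	0.323	-0.278	-0.581	-0.894	-0.099	-1.89	-0.74	0.575
Stability	0.584	-0.196	-0.508	1.501	-1.505	1.386	-0.149	0.753	-0.111	-0.005	0.052	-0.297	-0.02	0.433	0.152	1.039
Stacking_energy	-0.601	0.583	-1.536	-1.277	0.376	-0.344	-0.827	1.971	-0.072	-0.23	2.363	-0.913	-0.288	-0.284	1.226	0.424
Sugimoto_dG	-1.879	1.338	0.864	0.521	1.091	0.41	-0.052	-1.028	1.232	1.259	1.099	0.28	-1.33	-1.571	1.596	0.201
Sugimoto_dH	-1.062	-0.224	0.879	-0.619	-0.503	-0.013	-1.249	-1.901	-1.095	-0.084	0.703	-1.803	-0.342	-1.076	0.426	0.496
Sugimoto_dS	1.566	0.774	0.286	1.728	-0.538	-0.896	-1.578	-3.086	-1.065	-0.602	-0.912	-0.096	0.701	-0.49	-1.552	0.097
Watson-Crick_interaction	-0.234	1.218	-0.299	0.706	-0.605	-0.758	2.141	0.677	-0.105	0.359	0.968	-0.94	0.748	0.586	-1.019	0.235
Twist	0.991	-0.706	3.163	-0.13	1.354	0.137	0.73	-0.574	0.718	0.73	0.609	1.485	1.52	0.047	1.012	-0.976
Tilt	0.8	1.532	0.675	-0.185	-0.48	-0.213	-0.998	-0.202	1.287	-0.738	-0.075	1.741	0.225	1.602	-1.26	-0.488
Roll	-0.85	-0.228	-1.489	0.898	-1.945	-0.745	-0.027	0.299	0.353	0.63	-1.662	0.099	-2.459	1.331	1.745	-1.526
Shift	0.016	-0.751	1.892	1.957	-0.101	-0.064	1.535	-0.477	1.112	-0.86	1.286	0.075	-0.458	-1.338	0.943	-0.65
Slide	-0.2	0.505	-1.515	-2.429	-1.202	-0.564	0.748	-0.773	1.021	-0.827	0.191	-0.25	-0.15	-1.248	-0.616	0.154
Rise	-0.961	0.031	0.444	-0.342	-0.02	1.383	-0.018	-0.455	0.837	1.139	2.342	-0.878	-1.224	-0.716	-0.922	-1.982
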