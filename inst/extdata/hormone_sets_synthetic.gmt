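response to abscisic acid	GO:0009737	AaG00001	AaG00047	AaG00049	AaG00062	AaG00102	AaG00114	AaG00129	AaG00145	AaG00227	AaG00236	AaG00311	AaG00319	AaG00334	AaG00340	AaG00342
response to auxin	GO:0009733	AaG00027	AaG00036	AaG00065	AaG00174	AaG00188	AaG00213	AaG00226	AaG00237	AaG00272	AaG00314	AaG00337	AaG00352	AaG00356	AaG00377	AaG00396
response to brassinosteroid	GO:0009741	AaG00001	AaG00012	AaG00025	AaG00040	AaG00089	AaG00108	AaG00113	AaG00157	AaG00203	AaG00213	AaG00245	AaG00253	AaG00335	AaG00380	AaG00392
response to cytokinin	GO:0009735	AaG00034	AaG00073	AaG00089	AaG00107	AaG00141	AaG00146	AaG00148	AaG00165	AaG00192	AaG00194	AaG00202	AaG00250	AaG00299	AaG00316	AaG00338
response to ethylene	GO:0009723	AaG00009	AaG00090	AaG00098	AaG00131	AaG00175	AaG00179	AaG00184	AaG00210	AaG00218	AaG00232	AaG00273	AaG00318	AaG00319	AaG00325	AaG00392
response to gibberellin	GO:0009739	AaG00004	AaG00047	AaG00066	AaG00068	AaG00131	AaG00203	AaG00213	AaG00222	AaG00223	AaG00252	AaG00264	AaG00269	AaG00273	AaG00365	AaG00386
response to jasmonic acid	GO:0009753	AaG00022	AaG00024	AaG00041	AaG00048	AaG00073	AaG00079	AaG00101	AaG00112	AaG00119	AaG00148	AaG00168	AaG00324	AaG00351	AaG00371	AaG00394
response to salicylic acid	GO:0009751	AaG00030	AaG00053	AaG00118	AaG00143	AaG00152	AaG00155	AaG00157	AaG00198	AaG00201	AaG00226	AaG00288	AaG00308	AaG00316	AaG00366	AaG00400
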