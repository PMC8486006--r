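taxon	genus	repeat_content_pct	total_repeat_count	variance_mean_ratio	chi2	df	p_value	dispersion
Astragalus acutirostris	Astragalus	2.72	42	0.90	36.10	40	0.707	Poisson
Astragalus agnicidus	Astragalus	3.29	46	1.21	48.48	40	0.336	Poisson
Astragalus americanus	Astragalus	3.23	51	0.93	36.40	39	0.822	Poisson
Astragalus ampullarioides	Astragalus	2.78	48	1.41	54.87	39	0.095	Poisson
Astragalus ampullarius	Astragalus	2.72	43	1.64	63.98	39	0.014	Overdispersed
Astragalus arrectus	Astragalus	2.65	46	1.79	69.67	39	0.004	Overdispersed
Astragalus bicristatus	Astragalus	3.17	49	1.52	59.38	39	0.039	Overdispersed
Astragalus bolanderi	Astragalus	2.55	42	1.32	51.33	39	0.179	Poisson
Astragalus calycosus	Astragalus	3.87	55	2.30	89.71	39	1.43e-05	Overdispersed
Astragalus clevelandii	Astragalus	2.79	41	1.29	50.23	39	0.215	Poisson
Astragalus flexuosus	Astragalus	2.99	46	1.27	50.67	40	0.241	Poisson
Astragalus gypsodes	Astragalus	3.65	53	1.50	58.59	39	0.045	Overdispersed
Astragalus lentiginosus var. diphysus	Astragalus	3.43	59	1.50	59.83	40	0.045	Overdispersed
Astragalus lentiginosus var. mokiacensis	Astragalus	3.65	57	1.55	62.17	40	0.028	Overdispersed
Astragalus malacus	Astragalus	3.48	53	1.66	64.92	39	0.011	Overdispersed
Astragalus mollissimus	Astragalus	3.79	55	2.19	85.46	39	5.06e-05	Overdispersed
Astragalus neglectus	Astragalus	2.77	50	1.47	57.20	39	0.060	Poisson
Astragalus nuttallianus	Astragalus	3.09	50	1.38	53.67	39	0.118	Poisson
Astragalus obscurus	Astragalus	2.67	47	1.39	54.28	39	0.106	Poisson
Astragalus pattersonii	Astragalus	3.18	49	1.33	52.00	39	0.159	Poisson
Astragalus pectinatus	Astragalus	3.32	53	1.13	45.25	40	0.524	Poisson
Astragalus serenoi	Astragalus	2.99	46	1.08	43.38	40	0.659	Poisson
Astragalus tephrodes	Astragalus	3.89	51	1.49	58.02	39	0.051	Poisson
Astragalus toanus	Astragalus	3.28	56	1.26	48.96	39	0.263	Poisson
Astragalus wootonii	Astragalus	2.74	47	1.38	53.67	39	0.118	Poisson
Astragalus bhotanensis	Astragalus	2.86	49	1.08	43.06	40	0.683	Poisson
Astragalus gummifer	Astragalus	3.19	46	1.53	61.33	40	0.033	Overdispersed
Astragalus membranaceus	Astragalus	3.10	50	1.44	57.53	40	0.072	Poisson
Astragalus mongholicus	Astragalus	2.88	45	1.46	58.55	40	0.059	Poisson
Astragalus nakaianus	Astragalus	3.10	50	1.44	57.53	40	0.072	Poisson
Oxytropis bicolor	Oxytropis	3.66	63	1.27	49.38	39	0.247	Poisson
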