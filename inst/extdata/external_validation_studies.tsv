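metabolite	p_external	fc_external	p_internal	fc_internal	n_external	n_internal	adj_combined_p_published	label_published
p-Cresol glucuronide	0.0021	2.15	0.00001	3.80	460	919	7.5e-06	Direction, Significance, & Magnitude
p-Cresol sulfate	0.0278	1.08	0.00008	1.55	460	919	2.3e-04	Direction, Significance, & Magnitude
FFA 20:3	0.0000	0.63	0.000	1.23	460	919	1.8e-06	Significance
FFA 20:4	0.0004	0.65	0.002	1.18	460	919	1.4e-04	Significance
Uridine	0.0300	0.91	0.003	1.18	460	919	3.0e-03	Significance
Phenylacetyl-L-glutamine	0.0023	1.57	0.008	1.27	460	919	1.5e-03	Direction, Significance, & Magnitude
FFA 18:2	0.0106	0.73	0.01	1.17	460	919	3.3e-03	Significance
Trigonelline	0.0119	0.53	0.03	0.73	460	919	9.5e-03	Direction, Significance, & Magnitude
Ubiquinone 1	0.0030	0.73	0.03	1.16	460	919	3.3e-03	Significance
FFA 14:1	0.0100	0.77	0.04	1.25	460	919	9.5e-03	Significance
Kynurenine	0.0113	0.86	0.05	0.93	460	919	1.3e-02	Direction & Significance
Biliverdin	0.0003	0.70	0.08	0.74	460	919	1.8e-03	Direction, Significance, & Magnitude
Pantothenic acid	0.0174	0.85	0.09	0.79	460	919	2.2e-02	Direction, Significance, & Magnitude
FFA 20:2	0.0090	0.76	0.09	1.12	460	919	1.6e-02	Significance
Indolelactic acid	0.0109	0.81	0.09	0.91	460	919	1.7e-02	Direction & Significance
FFA 22:5	0.0002	0.63	0.17	1.09	460	919	2.3e-03	Significance
FFA 19:1	0.0179	0.78	0.18	1.15	460	919	3.3e-02	Significance
Cortisol	0.0165	1.21	0.19	1.12	460	919	3.3e-02	Direction & Significance
FFA 20:0	0.0307	0.87	0.19	0.88	460	919	5.1e-02	Direction & Significance
cis-Aconitic acid	0.0078	0.83	0.25	0.90	460	919	2.9e-02	Direction & Significance
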