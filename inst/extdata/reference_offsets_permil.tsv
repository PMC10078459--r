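year	Maentwrog	AliceHolt	Dartmoor	Sandringham	Tomich	MillHaft	Aviemore	Lanlas	Tweed	Mapledurham	Woburn	Lochwood
1979	0.09	0.40	0.22	0.60	0.69	0.38	1.75	0.17	0.68	1.21	2.52	0.18
1980	0.17	1.02	0.72	0.43	0.38	0.68	0.65	0.13	0.74	0.92	2.01	0.50
1981	0.28	0.69	1.14	0.40	0.99	0.18	0.13	0.23	0.06	0.58	2.44	0.47
1982	0.18	0.16	0.85	0.35	1.22	0.42	0.07	0.03	0.66	0.97	1.92	0.33
1983	0.49	0.75	1.42	0.53	1.14	0.70	0.28	0.95	0.21	1.39	2.33	0.86
1984	0.13	0.72	1.44	0.90	1.01	0.66	0.47	1.53	0.21	1.62	1.69	0.99
1985	0.44	0.17	1.05	0.30	1.33	0.52	0.33	0.72	0.69	1.02	0.81	1.05
1986	0.39	0.20	0.79	0.18	0.19	0.28	1.59	0.19	1.40	1.27	1.42	0.78
1987	0.01	0.46	0.73	0.43	1.30	0.99	0.68	0.54	0.99	1.01	0.91	0.72
1988	0.82	0.42	0.98	0.42	1.31	0.00	1.05	0.48	1.42	1.14	1.47	0.25
1989	1.50	0.66	0.93	0.00	0.70	0.68	0.47	0.96	0.36	1.66	1.70	0.16
1990	1.23	0.85	0.74	0.29	1.05	0.57	0.40	1.47	0.45	1.16	2.31	0.26
1991	0.76	0.96	0.52	0.51	0.89	0.74	0.28	1.07	0.64	1.74	2.24	0.36
1992	1.07	1.37	0.84	0.34	1.24	0.56	0.03	0.25	0.50	1.85	1.37	0.43
1993	1.03	0.65	0.93	0.16	0.93	1.06	0.69	0.15	1.15	1.10	1.45	0.22
1994	1.00	1.51	0.95	0.40	0.61	1.09	0.60	0.78	0.60	1.71	2.17	1.42
1995	0.82	1.21	0.94	0.47	1.46	1.12	1.37	1.47	0.22	0.57	1.88	0.54
1996	0.44	1.32	0.42	0.95	1.19	0.86	0.35	0.76	0.76	1.27	1.97	0.32
1997	0.14	1.30	1.50	0.69	1.05	1.34	1.24	0.88	1.09	1.89	2.20	0.44
1998	1.08	1.10	0.65	0.46	1.11	0.70	0.17	0.06	1.67	0.88	1.34	0.00
1999	0.26	1.16	1.24	0.12	0.78	0.67	0.57	0.65	1.25	1.57	1.77	0.15
2000	0.20	1.09	0.99	0.20	1.05	0.94	1.09	0.55	0.95	1.16	2.09	0.18
2001	0.20	1.80	1.23	0.44	0.70	1.25	0.57	0.27	0.80	1.64	2.07	0.50
2002	0.25	1.48	1.95	0.18	1.17	1.66	0.31	0.50	0.61	1.64	2.55	0.42
2003	0.75	1.01	1.26	0.50	0.59	0.81	1.06	0.92	0.67	1.58	1.81	0.82
2004	0.47	1.35	1.24	0.06	0.93	1.26	0.38	0.60	0.94	1.86
2005	0.43	1.55	1.40	0.82	0.13	0.76	0.68	0.22	0.92	1.80
2006	0.20	1.58	1.35	0.05	0.94	0.94	1.09	0.94	0.43	1.68
2007	0.20	1.13	1.26	0.20	1.06	1.16	0.80	0.01	1.03
2008	0.39	1.37	1.42	0.05	1.08	0.91	1.34	0.02	1.02
2009	1.36	1.68	1.53	0.04	1.14	2.09	1.93	0.98	0.28
2010	0.27	1.30	1.04	0.03	0.95	1.23	1.11	0.11
2011	0.24	1.16	1.30	0.46	0.76	1.00	1.65
2012	0.86	1.64	1.52	0.43	0.14	1.29	1.50
2013	0.24	1.80	1.35	0.53	0.10	0.93
2014	0.52	1.89	1.15	0.27	0.60	0.55
2015	0.33	1.52	1.69	0.15
2016	0.36
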