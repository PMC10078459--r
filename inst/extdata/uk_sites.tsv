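site_id	latitude	longitude	elevation_m	species	first_year	last_year
Maentwrog	52.95	-3.99	41	Q. petraea	1979	2016
AliceHolt	51.18	-0.85	107	Q. robur	1979	2015
Dartmoor	50.67	-3.84	217	Q. petraea	1979	2015
Sandringham	52.83	0.50	38	Q. robur	1979	2015
Tomich	57.30	-4.80	184	Q. petraea	1979	2014
MillHaft	52.80	-2.30	108	Q. robur	1979	2014
Aviemore	57.15	-3.84	300	Q. robur	1979	2012
Lanlas	52.22	-4.22	111	Q. petraea	1979	2010
Tweed	55.55	-2.80	190	Q. robur	1979	2009
Mapledurham	51.50	-1.00	70	Q. robur/Q. petraea	1979	2006
Woburn	51.98	-0.58	150	Q. robur	1979	2003
Lochwood	55.27	-3.43	175	Q. robur	1979	2003
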