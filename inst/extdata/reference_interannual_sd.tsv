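site_id	sd_model	sd_obs
Maentwrog	0.28	0.57
AliceHolt	0.29	0.50
Dartmoor	0.25	0.39
Sandringham	0.27	0.53
Tomich	0.27	0.37
MillHaft	0.30	0.64
Aviemore	0.30	0.90
Lanlas	0.26	0.65
Tweed	0.30	0.62
Mapledurham	0.31	0.43
Woburn	0.31	0.55
Lochwood	0.29	0.65
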