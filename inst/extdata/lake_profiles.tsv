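code	location	region	category	tidal_fraction	area_1000m2	max_depth_m	temperature_c	salinity_ppt	n_passed_qc	lineage	pi	he
Sea Australia	Australia	Australia	open	NA	NA	NA	NA	NA	7	B	0.0095	0.117
Sea Indonesia	Berau	Kalimantan	open	NA	NA	NA	29.0	33.5	5	B	0.0101	0.157
Kalimantan1	Berau: Kakaban	Kalimantan	low	0.1	4900	12	30.0	23.5	20	A	NA	NA
Kalimantan2	Berau: Tanah Banban	Kalimantan	low	0.4	232	NA	29.5	26.0	2	B	0.0074	0.034
Kalimantan3	Berau: Maratua	Kalimantan	medium	0.5	140	17	29.5	27.0	26	B	0.0050	0.081
Papua27	Papua: Wayag	Papua	medium	NA	22	2	29.5	31.0	5	B	0.0037	0.038
Papua30	Papua: Wayag	Papua	high	0.8	13	4	32.4	28.9	8	B	0.0045	0.052
Papua32	Papua: Wayag	Papua	medium	0.5	6	6	31.2	30.7	4	B	0.0053	0.059
Papua1	Papua: Gam	Papua	low	0.1	89	19	32.3	24.0	11	B	0.0036	0.054
Papua4	Papua: Misool	Papua	high	0.8	14	20	31.7	25.9	19	B	0.0047	0.080
Papua5	Papua: Misool	Papua	low	0.3	4	5	31.5	28.9	18	B	0.0060	0.095
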