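accession	Guatemalan	Mexican	Lowland
069-02	37.61	62.39	0.00
263-C	0.00	0.00	1.00
Anaheim	93.06	6.94	0.00
Bacon	37.69	62.31	0.00
Carlsbad	1.00	0.00	0.00
CH-CR-25	50.01	7.98	42.01
CH-G-07	84.08	0.00	15.92
CH-G-10	89.28	0.00	10.72
CH-G-11	89.96	0.00	10.04
Fairchild	0.00	0.00	1.00
Fuerte	58.48	41.52	0.00
Ganter	0.00	1.00	0.00
Gwen	1.00	0.00	0.00
Hass	1.00	0.00	0.00
Linda	1.00	0.00	0.00
Lyon	83.78	16.22	0.00
Mendez	1.00	0.00	0.00
Nabal	1.00	0.00	0.00
Nimlioh	1.00	0.00	0.00
PequenoCharly	0.00	1.00	0.00
Pinkerton	81.00	19.00	0.00
Reed	1.00	0.00	0.00
Simmonds	0.00	0.00	1.00
Taft	1.00	0.00	0.00
Thille	1.00	0.00	0.00
TopaTopa	0.00	1.00	0.00
VC26	0.00	0.00	1.00
Velvick	59.18	0.00	40.82
Waldin	0.00	0.00	1.00
Zutano	38.35	61.65	0.00
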