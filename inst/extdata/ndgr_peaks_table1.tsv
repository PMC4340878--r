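peak_position	summit	score	fold_enrichment	motif_position	consensus_sequence
1662185-1663375	1662816	197.21	4.41	1662781-1662795	GTCCACCCACCGGAC
1827404-1829415	1828601	768.68	6.04	1828423-1828437	GTCCACCACGCGGAC
1896843-1898738	1897467	276.74	5.04	1897508-1897522	GTCCATCCTGCGGAC
2261363-2262539	2261945	101.39	3.54	2261989-2262003	GTCCACCCTTTGGAC
3161458-3164611	3163260	370.89	4.20	3163207-3163221	GATCACACTCCGGAA
3268432-3272122	3269947	139.50	4.06	3269922-3269936	GTTCACCTCGTGGTC
3702919-3706333	3704715	225.72	4.78	3704846-3704860	TTCCACCTTGATCAC
4578730-4584188	4580680	129.09	5.24	4580694-4580708	TCCCACTCCTTGGAC
4600435-4603056	4601769	162.13	4.23	4601788-4601802	GGTCAGCTCCTGGAC
5625694-5627962	5626280	123.46	3.01	N.A.	N.A.
5741825-5743033	5742489	133.14	3.08	5742420-5742434	GACCACCTCGTGGAC
5862424-5864373	5863498	180.16	4.28	5863483-5863497	GTCCACACCGTGGAC
5880856-5884347	5882679	160.34	3.32	5882573-5882587	GTCCGCCTTGAGGAC
6001446-6003903	6002834	279.72	3.77	6002862-6002876	TCCCACCCACTTGAC
6013959-6016845	6015210	329.68	5.54	6015204-6015218	GTCCGCCATGCGGAC
6048531-6053535	6051804	218.57	4.40	6051783-6051797	GTCCAGAACGCCGAC
6059038-6060496	6059807	175.83	4.20	6059774-6059788	GTCCAGCAAGTGGAC
6701783-6704095	6702908	291.94	3.29	6702861-6702875	GTCCACATTTTGGAT
7199604-7200985	7200371	425.57	5.00	7200390-7200404	TTTTGCCATGTGGAC
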