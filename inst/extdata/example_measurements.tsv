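synthetic amino-acid labeling example
		chrom_001	chrom_002	chrom_003	chrom_004	chrom_005	chrom_006
Gly	245	62762.5320011143	62390.596305593	62436.9110031571	62631.206223256	62318.1065559359	61543.1633903386
Gly	246	580783.11811137	577061.382622693	579744.032960095	572509.767269813	572910.574437194	577697.383608109
Gly	247	184111.758192023	185880.229732991	181632.030483026	182416.594820859	184077.403861231	183410.029096871
Gly	248	175994.000104128	180497.059508711	178837.841395317	181193.553065583	176189.218139727	176876.27020172
Ala	259	17613.0245949521	18056.6114471238	18204.1132242383	17634.0805505936	18321.4868548776	18257.2866902297
Ala	260	174414.65904277	170028.077635197	174804.507557833	177910.993020704	175783.932901527	176644.161044674
Ala	261	122566.235453149	123940.245215945	121765.652913388	121965.066907575	122386.933459908	123982.27189699
Ala	262	121584.160366054	122148.648345282	123552.572939063	121503.563839598	121066.309055457	121634.189263238
Ala	263	554631.23701754	562381.539076056	565669.62487974	560088.81609358	572183.283057951	555383.915458414
Ala	231	29675.4839675368	30054.3442694592	29806.5879733801	29330.1429270672	29516.4149240385	29799.9305533452
Ala	232	269280.116155826	270271.169291301	267938.839372078	270608.086688521	272977.842444854	276095.658835568
Ala	233	126358.941125103	124821.161995702	125980.37475921	124796.52049261	124018.743966961	124583.763058436
Ala	234	577086.67216834	570380.301549935	572637.479149686	566808.202514643	573246.946080721	575721.792375009
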