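sample_id	utr5	splice	synonymous	non_synonymous	intronic	utr3	up_down	intergenic
YE.1	57391	125	30613	10615	1607168	61687	9424	1084836
YE.2	60590	112	33166	11951	1684661	67325	9837	1127935
YE.3	58248	134	32744	11700	1662763	63397	9474	1089767
YE.4	59597	118	31710	11206	1671684	64494	9791	1116326
YE.5	77569	177	41578	14321	2171599	84188	12713	1447039
YE.6	54333	121	30105	10192	1547760	60042	9140	1023064
YE.7	59112	149	31765	10628	1632537	64367	9600	1085012
YE.8	67792	150	36184	12314	1901127	73891	10832	1276499
YE.9	77505	154	41539	14524	2131764	84826	12549	1438706
YE.10	61007	124	32784	11658	1666449	65284	9866	1128659
YE.11	58464	123	31430	10475	1623541	63048	9434	1079978
YE.12	66266	152	34974	12446	1819685	72023	10751	1223139
YE.13	62411	122	32830	11287	1708629	67977	9937	1167553
YE.14	62633	140	33327	11840	1735879	67548	10102	1160186
YE.15	57282	146	30406	10878	1565366	61424	9139	1057823
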