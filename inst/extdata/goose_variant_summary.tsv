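sample_id	n_snp	n_ti	n_tv	n_het	n_hom
YE.1	4249848	3026441	1223407	2033435	2216413
YE.2	4516551	3212443	1304108	2265592	2250959
YE.3	4193357	2986922	1206435	1925688	2267669
YE.4	4521725	3214828	1306897	2229089	2292636
YE.5	4868607	3464303	1404304	2517574	2351033
YE.6	4069187	2896573	1172614	1825696	2243491
YE.7	4116905	2934630	1182275	1952927	2163978
YE.8	4427089	3153851	1273238	2388968	2038121
YE.9	4634450	3308984	1325466	2358672	2275778
YE.10	4442781	3168351	1274430	2221703	2221078
YE.11	4264640	3033130	1231510	1969277	2295363
YE.12	4725693	3372046	1353647	2609066	2116627
YE.13	4518224	3215974	1302250	2106137	2412087
YE.14	4655819	3314398	1341421	2428996	2226823
YE.15	4231364	3018327	1213037	1952839	2278525
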