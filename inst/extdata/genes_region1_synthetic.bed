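6	109576122	109605997	GENE001
6	109714589	109722043	GENE002
6	109857475	109890771	GENE003
6	110041606	110068458	GENE004
6	110218372	110249488	GENE005
6	110247833	110255385	GENE006
6	110266983	110316370	GENE007
6	110599893	110622004	GENE008
6	110657342	110706619	GENE009
6	110705952	110760730	GENE010
6	110801701	110824481	GENE011
6	110950479	111000909	GENE012
6	111030024	111037842	GENE013
6	111066850	111086032	GENE014
6	111177329	111195267	GENE015
6	111258346	111263863	GENE016
6	111287807	111326520	GENE017
6	111304011	111347127	GENE018
6	111603040	111631570	GENE019
6	111726777	111782622	GENE020
6	112136285	112156601	GENE021
6	112301267	112311878	GENE022
6	112385231	112433972	GENE023
6	112422057	112440726	GENE024
6	112822727	112849556	GENE025
6	112953828	113007586	GENE026
6	113176259	113222301	GENE027
6	113266115	113285308	GENE028
6	114073347	114126835	GENE029
6	114170569	114210681	GENE030
6	114295778	114340686	GENE031
6	114641945	114696197	GENE032
6	115094172	115134286	GENE033
6	115142783	115147874	GENE034
6	115157513	115202630	GENE035
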