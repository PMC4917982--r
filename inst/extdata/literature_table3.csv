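study,species,m0_g,ratio,r2,s_printed,media,root_state,flags
Chloupek 1972,Zea mays,,,0.728,,Sand,dried,incomplete
Chloupek 1972,Allium cepa,,,0.545,,Sand,dried,incomplete
Chloupek 1972,Helianthus annuus,,,0.897,,Sand,dried,incomplete
Chloupek 1972,Avena sativa,,,0.464,,Clay soil,dried,incomplete
Chloupek 1972,Helianthus annuus,,,0.432,,Clay soil,dried,incomplete
Chloupek 1972,Brassica napus,,,0.081,,,fresh,incomplete
Chloupek 1977,Daucus carota,,,0.514,,Loam (field),fresh,incomplete
Chloupek 1977,Helianthus annuus,,,0.566,,Sand,fresh,incomplete
Kendall et al. 1982,Medicago sativa,0.2,0.03,0.50,0.48,Silt loam (field),dried,
Kendall et al. 1982,Trifolium pratense,,,0.67,,Hydroponics,dried,incomplete
Dalton 1995,Solanum lycopersicum,2,0.17,0.77,0.57,Hydroponics,dried,inconsistent_printed
van Beem et al. 1998,Zea mays,100,0.17,0.53,0.44,Loam (field),fresh,
van Beem et al. 1998,Zea mays,5,1.33,0.73,0.00,Vermiculite,fresh,
Ozier-Lafontaine and Bajazet 2005,Solanum lycopersicum,1,0.55,0.82,0.36,Clay loam,dried,
Ozier-Lafontaine and Bajazet 2005,Solanum lycopersicum,10,,0.99,0.99,Hydroponics,dried,incomplete
Aulen and Shipley 2012,Herbaceous species,,0.10,0.30,0.30,Compost,dried,ambiguous_source
Dietrich et al. 2013,Triticum aestivum,1,0.32,0.75,0.51,Sand,dried,
Ellis et al. 2013,Vicia faba,10,0.48,0.31,0.16,Sheep manure,fresh,
Wheat multi-soil benchmark,Triticum turgidum ssp. durum,1,0.09,0.787,0.72,"Silt loam, loam, sandy loam",dried,
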