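species,length_m
Adamantisaurus mezzalirai,NA
Aeolosaurus colhuehuapiensis,NA
Aeolosaurus rionegrinus,NA
Antarctosaurus wichmannianus,NA
Argyrosaurus superbus,NA
Atacamatitan chilensis,NA
Barrosasaurus casamiquelai,NA
Baurutitan britoi,NA
Bonitasaura salgadoi,NA
Bonatitan reigi,NA
Gondwanatitan faustoi,NA
Laplatasaurus araukanicus,NA
Maxakalisaurus topai,NA
Narambuenatitan palomoi,NA
Neuquensaurus australis,NA
Panamericansaurus schroederi,NA
Pellegrinisaurus powelli,NA
Pitekunsaurus macayai,NA
Puertasaurus reuili,30
Rocasaurus muniozi,8
Saltasaurus loricatus,NA
Trigonosaurus pricei,NA
Uberabatitan ribeiroi,NA
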