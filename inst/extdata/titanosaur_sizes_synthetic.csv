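species,length_m
Adamantisaurus mezzalirai,10.25
Aeolosaurus colhuehuapiensis,29.21
Aeolosaurus rionegrinus,8.05
Antarctosaurus wichmannianus,17.50
Argyrosaurus superbus,24.34
Atacamatitan chilensis,10.80
Barrosasaurus casamiquelai,13.60
Baurutitan britoi,20.28
Bonitasaura salgadoi,21.24
Bonatitan reigi,8.64
Gondwanatitan faustoi,18.61
Laplatasaurus araukanicus,27.26
Maxakalisaurus topai,14.03
Narambuenatitan palomoi,8.58
Neuquensaurus australis,15.46
Panamericansaurus schroederi,18.30
Pellegrinisaurus powelli,16.09
Pitekunsaurus macayai,26.72
Puertasaurus reuili,30.00
Rocasaurus muniozi,8.00
Saltasaurus loricatus,23.35
Trigonosaurus pricei,13.52
Uberabatitan ribeiroi,27.97
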