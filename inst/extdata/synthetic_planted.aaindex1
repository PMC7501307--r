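H PLNT0001
D planted bit 1 of the ground-truth code
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    2.8423937011975795  0.5536120149074123  2.1012597347842528  2.3756518793292343  0.69044492414686831  2.1545400721719488  2.7081615104340018  0.17670486029237509  2.7674032696289941  0.79147490991745151
    0.17858942623715848  2.0975907295476643  2.666676474479027  0.74769023784901945  0.75097768439445645  0.84634239231236286  0.74746506346855313  2.5093456084607171  2.174847668176517  0.22124084089882673
//
H PLNT0002
D planted bit 2 of the ground-truth code
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    2.7248724866891281  0.10555214344058186  0.50805841048713773  2.675369709613733  2.6202552154660226  2.197255733702332  0.88571332474239173  0.46520960179623216  2.7109752436634151  0.75854527016635986
    2.8409576917532831  0.37135227480903271  0.36712519093416635  2.8488115559797733  0.67969096479937441  0.24056288623251021  0.67401924440637229  2.621877932851203  2.6890025756787508  2.8704847718821838
//
H PLNT0003
D planted bit 3 of the ground-truth code
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    2.8657614177325739  0.75072313752025366  2.2804920439841228  0.66417013120371848  0.26449020628351722  2.4650415794225409  2.8752400135155769  2.729428908531554  0.36101468084380034  2.4651066449936478
    2.5735334480414167  2.2301206921925769  0.38743683896027509  0.48908314208965747  0.17747166173066944  2.8178474469576029  2.5471931874053553  0.41096141820307824  0.71412674454040825  0.033939303061924879
//
H PLNT0004
D planted bit 4 of the ground-truth code
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    2.0242307443171739  0.011325386166572571  0.86586878320667893  0.60967782132793225  2.8558207255322485  0.19357521927449853  2.4654558830661699  0.72006137380376456  0.74594821978826076  2.8656709528993813
    2.0200305795529858  0.52725628274492919  0.63339915925171231  0.04269219639245421  2.5808405035175381  0.37142616505734621  2.7639973293757065  2.5426940720062703  2.5665986825479195  2.1725596512667833
//
H PLNT0005
D planted bit 5 of the ground-truth code
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    2.1502369340509175  0.6284653851762414  2.1265585747547449  0.52574231699109075  0.87100821461062883  0.8966658513760194  2.4604057817952709  0.85496367907617243  2.8495992226991804  0.37794708330184223
    2.71643184942659  0.11859112693928182  0.48052233683411033  0.60197300557047129  2.69644636514131  2.7044643878936769  2.8951878726948053  2.047893538000062  0.83756812345236542  2.0017341013532133
//
H NOIS0001
D noise feature (size-filter ineligible)
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092
    17.133062744978815  11.347128241322935  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092  0.044470121548511092
//
H NOIS0002
D noise feature (size-filter ineligible)
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475  11.08097346033901  0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475
    0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475  0.08539300539996475  15.758065953850746  0.08539300539996475  0.08539300539996475  0.08539300539996475
//
H NOIS0003
D noise feature (size-filter ineligible)
I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V
    0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818  16.521590547636151  0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818
    0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818  0.055860539712011818  15.605476771015674  0.055860539712011818  0.055860539712011818  0.055860539712011818
//
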