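name,formula,monoisotopic_mass,source,class
alkyl R-group carboxylate,C5H9O2,101.060255,chebi,R-group
creatinine,C4H7N3O,113.058912,hmdb,urinary metabolite
nicotinamide,C6H6N2O,122.048013,hmdb,vitamin B3
taurine,C2H7NO3S,125.014664,hmdb,amino sulfonic acid
2-hydroxyethanesulfonate,C2H6O4S,125.99868,hmdb,organosulfonate
metformin,C4H11N5,129.101445,chebi,drug
L-leucine,C6H13NO2,131.094629,hmdb,amino acid
hypoxanthine,C5H4N4O,136.038511,hmdb,purine
salicylic acid,C7H6O3,138.031694,hmdb,drug metabolite
L-glutamic acid,C5H9NO4,147.053158,hmdb,amino acid
"2,3-dihydroxybutanedioic acid",C4H6O6,150.016438,chebi,sugar acid
acetaminophen,C8H9NO2,151.063329,hmdb,drug
xanthine,C5H4N4O2,152.033425,hmdb,purine
acesulfame,C4H5NO4S,162.993929,hmdb,sweetener
L-phenylalanine,C9H11NO2,165.078979,hmdb,amino acid
1-methylxanthine,C6H6N4O2,166.049075,hmdb,xanthine alkaloid
urate,C5H4N4O3,168.02834,hmdb,purine
2-furoylglycine,C7H7NO4,169.037508,hmdb,acyl glycine
pyridoxine,C8H11NO3,169.073893,hmdb,vitamin B6
gabapentin,C9H17NO2,171.125929,chebi,drug
indole-3-acetic acid,C10H9NO2,175.063329,hmdb,indole
cotinine,C10H12N2O,176.094963,hmdb,nicotine metabolite
hippuric acid,C9H9NO3,179.058243,hmdb,acyl glycine
cyclamate,C6H13NO3S,179.061614,hmdb,sweetener
D-glucose,C6H12O6,180.063388,hmdb,carbohydrate
theobromine,C7H8N4O2,180.064726,hmdb,xanthine alkaloid
theophylline,C7H8N4O2,180.064726,hmdb,xanthine alkaloid
paraxanthine,C7H8N4O2,180.064726,hmdb,xanthine alkaloid
3-methoxyacetaminophen,C9H11NO3,181.073893,hmdb,drug metabolite
L-tyrosine,C9H11NO3,181.073893,hmdb,amino acid
1-methyluric acid,C6H6N4O3,182.04399,hmdb,caffeine metabolite
saccharin,C7H5NO3S,182.999014,hmdb,sweetener
3-methoxy-4-hydroxyphenylglycol,C9H12O4,184.073559,hmdb,catechol
p-cresol sulfate,C7H8O4S,188.01433,hmdb,phenol sulfate
citric acid,C6H8O7,192.027003,hmdb,tricarboxylic acid
trans-3'-hydroxycotinine,C10H12N2O2,192.089878,hmdb,nicotine metabolite
D-glucuronic acid,C6H10O7,194.042653,hmdb,uronic acid
5-dehydro-L-gluconate,C6H10O7,194.042653,hmdb,sugar acid
caffeine,C8H10N4O2,194.080376,hmdb,xanthine alkaloid
polyethylene glycol polymer n4,C8H18O5,194.115424,chebi,polymer
N-acetyl-5-aminosalicylic acid,C9H9NO4,195.053158,hmdb,drug metabolite
6-hydroxy-3-succinoylpyridine,C9H9NO4,195.053158,hmdb,nicotine metabolite
"1,7-dimethyluric acid",C7H8N4O3,196.05964,hmdb,caffeine metabolite
5-acetylamino-6-amino-3-methyluracil,C7H10N4O3,198.07529,hmdb,caffeine metabolite
lauric acid,C12H24O2,200.17763,lipidmaps,fatty acid
N-octanoylglycine,C10H19NO3,201.136493,metacyc,acyl glycine
L-tryptophan,C11H12N2O2,204.089878,hmdb,amino acid
pantothenol,C9H19NO4,205.131408,hmdb,vitamin B5 precursor
ibuprofen,C13H18O2,206.13068,chebi,drug
indoxyl sulfate,C8H7NO4S,213.009579,hmdb,arylsulfate
threoninyl-proline,C9H16N2O4,216.111007,metacyc,dipeptide
pantothenate,C9H17NO5,219.110673,hmdb,vitamin B5
myristic acid,C14H28O2,228.20893,lipidmaps,fatty acid
N-decanoylglycine,C12H23NO3,229.167794,metacyc,acyl glycine
naproxen,C14H14O3,230.094294,chebi,drug
acetaminophen sulfate,C8H9NO5S,231.020143,hmdb,drug metabolite
rhombifoline,C14H20N2O,232.157563,metacyc,alkaloid
carbamazepine,C15H12N2O,236.094963,chebi,drug
felbamate,C11H14N2O4,238.095357,chebi,drug
biotin,C10H16N2O3S,244.088163,hmdb,vitamin B7
sulfamethoxazole,C10H11N3O3S,253.052112,chebi,drug
midodrine,C12H18N2O4,254.126657,chebi,drug
palmitic acid,C16H32O2,256.24023,lipidmaps,fatty acid
N-lauroylglycine,C14H27NO3,257.199094,metacyc,acyl glycine
caffeic acid 4-sulfate,C9H8O7S,259.999074,hmdb,phenol sulfate
ropinirole,C16H24N2O,260.188863,chebi,drug
3-methoxy-4-hydroxyphenylglycol sulfate,C9H12O7S,264.030374,hmdb,catechol sulfate
phenylacetylglutamine,C13H16N2O4,264.111007,hmdb,amino acid conjugate
atenolol,C14H22N2O3,266.163043,chebi,drug
girgensonine,C16H20N2O2,272.152478,metacyc,alkaloid
ferulic acid 4-sulfate,C10H10O7S,274.014724,hmdb,phenol sulfate
venlafaxine,C17H27NO2,277.204179,chebi,drug
linoleic acid,C18H32O2,280.24023,lipidmaps,fatty acid
threoninyl-tyrosine,C13H18N2O5,282.121572,metacyc,dipeptide
oleic acid,C18H34O2,282.25588,lipidmaps,fatty acid
p-cresol glucuronide,C13H16O7,284.089603,hmdb,phenol glucuronide
stearic acid,C18H36O2,284.27153,lipidmaps,fatty acid
benzoylecgonine,C16H19NO4,289.131408,hmdb,drug metabolite
acetylsulfamethoxazole,C12H13N3O4S,295.062677,chebi,drug metabolite
4'-N-desmethylolanzapine,C16H18N4S,298.125218,chebi,drug metabolite
uric acid riboside,C10H12N4O7,300.070599,hmdb,purine conjugate
indoxyl glucuronide,C14H15NO7,309.084852,hmdb,indole conjugate
"15,16-DiHODE",C18H32O4,312.23006,lipidmaps,oxylipin
acetohexamide,C15H20N2O4S,324.114378,chebi,drug
acetaminophen glucuronide,C14H17NO8,327.095417,hmdb,drug metabolite
6-keto-decanoylcarnitine,C17H31NO5,329.220223,hmdb,acyl carnitine
neomenthol-glucuronide,C16H28O7,332.183503,hmdb,glucuronide
amifloxacin,C16H19FN4O3,334.144119,chebi,drug
15(S)-HPETE,C20H32O4,336.23006,lipidmaps,eicosanoid
estrone 3-sulfate,C18H22O5S,350.118795,hmdb,steroid sulfate
dehydroepiandrosterone sulfate,C19H28O5S,368.165745,hmdb,steroid sulfate
riboflavin,C17H20N4O6,376.138284,hmdb,vitamin B2
reduced riboflavin,C17H22N4O6,378.153934,hmdb,vitamin B2
deoxycholic acid,C24H40O4,392.29266,hmdb,bile acid
sucralose,C12H19Cl3O8,396.014551,hmdb,sweetener
cholic acid,C24H40O5,408.287574,hmdb,bile acid
folate,C19H19N7O6,441.139681,hmdb,vitamin B9
glycochenodeoxycholic acid,C26H43NO5,449.314123,hmdb,bile acid conjugate
glycodeoxycholic acid,C26H43NO5,449.314123,hmdb,bile acid conjugate
glycocholic acid,C26H43NO6,465.309038,hmdb,bile acid conjugate
etiocholanolone glucuronide,C25H38O8,466.256668,hmdb,steroid glucuronide
androsterone glucuronide,C25H38O8,466.256668,hmdb,steroid glucuronide
taurocholic acid,C26H45NO7S,515.291674,hmdb,bile acid conjugate
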