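disease,phenotype,penetrance_pct,group_id
Down syndrome,Short face,100,ds1
Down syndrome,Upward slanting eyes,100,ds2
Down syndrome,Epicanthus,100,ds3
Down syndrome,Brushfield spots,100,ds4
Down syndrome,Low-set ears,100,ds5
Down syndrome,Small ears,100,ds6
Down syndrome,Flattened nose,100,ds7
Down syndrome,Small mouth,100,ds8
Down syndrome,Protruding tongue,100,ds9
Acromegaly,Forehead bulge,100,ac1
Acromegaly,Prominent jaw,100,ac2
Acromegaly,Prominent zygomatic arch,100,ac3
Acromegaly,Deep nasolabial folds,100,ac4
Acromegaly,Enlarged nose,100,ac5
Acromegaly,Enlarged brow,100,ac6
Acromegaly,Enlarged ear,100,ac7
Acromegaly,Enlarged lip,100,ac8
Cornelia de Lange syndrome,Short face,82.7,cdl1
Cornelia de Lange syndrome,Small jaw,82.7,cdl2
Cornelia de Lange syndrome,Arched eyebrows,82.7,cdl3
Cornelia de Lange syndrome,Joined eyebrows,82.7,cdl4
Cornelia de Lange syndrome,Short nose,82.7,cdl5
Cornelia de Lange syndrome,Forward nostril,82.7,cdl6
Cornelia de Lange syndrome,Long philtrum,82.7,cdl7
Cornelia de Lange syndrome,Thin upper lip,82.7,cdl8
Cornelia de Lange syndrome,Upturned corners of the mouth,82.7,cdl9
Angelman syndrome,Narrow bifrontal diameter,100,an1
Angelman syndrome,Huge jaw,100,an2
Angelman syndrome,Almond-shaped palpebral fissures,100,an3
Angelman syndrome,Narrow nasal bridge,100,an4
Angelman syndrome,Thin upper lip,100,an5
Angelman syndrome,Protruding tongue,100,an6
Cushing's syndrome,Red face,100,cu1
Cushing's syndrome,Full moon face,100,cu2
Cushing's syndrome,Acne,100,cu3
Cushing's syndrome,Excessive hair,100,cu4
Cushing's syndrome,Chemosis conjunctiva,100,cu5
Fetal alcohol spectrum disorders,Small head,100,fa1
Fetal alcohol spectrum disorders,Short palpebral fissures,100,fa2
Fetal alcohol spectrum disorders,Smooth philtrum,100,fa3
Fetal alcohol spectrum disorders,Thin vermilion border of the upper lip,100,fa4
Turner syndrome,Small jaw,56,tu1
Turner syndrome,Epicanthus,56,tu2
Turner syndrome,Ptosis,56,tu3
Turner syndrome,Ocular hypertelorism,56,tu4
Turner syndrome,Low-set ears,56,tu5
Turner syndrome,Multiple facial nevi,56,tu6
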