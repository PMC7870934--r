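# synthetic compound vocabulary: natural-product SMILES used to label generated compounds; structures are illustrative stand-ins, not curated assignments
compound_name	smiles
quercetin	O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
apigenin	O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12
luteolin	O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
chrysin	O=c1cc(-c2ccccc2)oc2cc(O)cc(O)c12
baicalein	O=c1cc(-c2ccccc2)oc2cc(O)c(O)c(O)c12
wogonin	COc1c(O)cc2oc(-c3ccccc3)cc(=O)c2c1O
oroxylin_a	COc1c(O)c2c(=O)cc(-c3ccccc3)oc2cc1O
baicalin	O=C(O)C1OC(Oc2cc3oc(-c4ccccc4)cc(=O)c3c(O)c2O)C(O)C(O)C1O
kaempferol	O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12
naringenin	O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21
genistein	O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12
daidzein	O=c1c(-c2ccc(O)cc2)coc2ccc(O)cc12
catechin	Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2
resveratrol	Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1
curcumin	COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O
magnolol	Oc1ccc(CC=C)cc1-c1cc(CC=C)ccc1O
chrysophanol	Cc1cc(O)c2c(c1)C(=O)c1c(O)cccc1C2=O
emodin	Cc1cc(O)c2c(c1)C(=O)c1cc(O)cc(O)c1C2=O
palmitic_acid	CCCCCCCCCCCCCCCC(=O)O
tetradecanol_1	CCCCCCCCCCCCCCO
caffeic_acid	O=C(O)/C=C/c1ccc(O)c(O)c1
ferulic_acid	COc1cc(/C=C/C(=O)O)ccc1O
gallic_acid	O=C(O)c1cc(O)c(O)c(O)c1
salicylic_acid	O=C(O)c1ccccc1O
menthol	CC(C)C1CCC(C)CC1O
limonene	CC(=C)C1CCC(C)=CC1
linalool	CC(C)=CCCC(C)(O)C=C
camphor	CC1(C)C2CCC1(C)C(=O)C2
eugenol	COc1cc(CC=C)ccc1O
thymol	Cc1ccc(C(C)C)c(O)c1
vanillin	COc1cc(C=O)ccc1O
coumarin	O=c1ccc2ccccc2o1
bergapten	COc1c2ccoc2cc2oc(=O)ccc12
scopoletin	COc1cc2ccc(=O)oc2cc1O
umbelliferone	O=c1ccc2ccc(O)cc2o1
osthole	COc1ccc2ccc(=O)oc2c1CC=C(C)C
paeonol	COc1ccc(C(C)=O)c(O)c1
cinnamaldehyde	O=C/C=C/c1ccccc1
gingerol_6	CCCCCC(O)CC(=O)CCc1ccc(O)c(OC)c1
berberine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc2c(cc1-3)OCO2
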