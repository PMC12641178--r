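gene_id	role	category	ko_ids
era	RBF	GTPase	K03595
der	RBF	GTPase	K03977
obgE	RBF	GTPase	K03979
hflX	RBF	GTPase	K03665
bipA	RBF	GTPase	K06207
lepA	RBF	GTPase	K03596
ychF	RBF	GTPase	K06942
engB	RBF	GTPase	K03978
rsgA	RBF	GTPase	K06949
rbgA	RBF	GTPase	K14540
yqeH	RBF	GTPase	
deaD	RBF	helicase	K05592
dbpA	RBF	helicase	K05591
srmB	RBF	helicase	K05590
rhlB	RBF	helicase	K03732
rhlE	RBF	helicase	K11927
rnc	RBF	ribonuclease	K03685
rne	RBF	ribonuclease	K08300
rng	RBF	ribonuclease	K08301
rnj	RBF	ribonuclease	K12574
rnb	RBF	ribonuclease	K01147
rnr	RBF	ribonuclease	K12573
rnt	RBF	ribonuclease	K03683
rph	RBF	ribonuclease	K00989
rnmV	RBF	ribonuclease	
pnp	RBF	ribonuclease	K00962
yqgF	RBF	ribonuclease	K07447
ybeY	RBF	ribonuclease	K07042
rnpA	RBF	ribonuclease	K03536
groEL	RBF	chaperone	K04077
groES	RBF	chaperone	K04078
dnaK	RBF	chaperone	K04043
dnaJ	RBF	chaperone	K03686
grpE	RBF	chaperone	K03687
rbfA	RBF	maturation	K02834
rimM	RBF	maturation	K02860
rimP	RBF	maturation	K09748
rsfS	RBF	maturation	K09710
yjgA	RBF	maturation	K09889
rimI	RBF	maturation	K03789
rimJ	RBF	maturation	
rimL	RBF	maturation	
yhbH	RBF	maturation	K05807
rmf	RBF	maturation	K03812
raiA	RBF	maturation	K05808
rel	RBF	other	K00951
yheS	RBF	other	K06158
fau-1	RBF	other	
sra	RBF	other	
rsmA	RBF	modification	K02528
rsmB	RBF	modification	K03500
rsmC	RBF	modification	K00564
rsmD	RBF	modification	K08316
rsmE	RBF	modification	K09761
rsmF	RBF	modification	
rsmG	RBF	modification	K03501
rsmH	RBF	modification	K03438
rsmI	RBF	modification	K07056
rsmJ	RBF	modification	
rlmA	RBF	modification	
rlmB	RBF	modification	K03218
rlmC	RBF	modification	
rlmD	RBF	modification	
rlmE	RBF	modification	K02427
rlmF	RBF	modification	
rlmG	RBF	modification	
rlmH	RBF	modification	
rlmI	RBF	modification	
rlmJ	RBF	modification	
rlmKL	RBF	modification	
rlmM	RBF	modification	
rlmN	RBF	modification	K06941
rluA	RBF	modification	K06177
rluB	RBF	modification	K06178
rluC	RBF	modification	K06179
rluD	RBF	modification	K06180
rluE	RBF	modification	
rluF	RBF	modification	
rsuA	RBF	modification	K06183
rimO	RBF	modification	K14441
tsaB	RBF	modification	K14742
tsaC	RBF	modification	K07566
tsaD	RBF	modification	K01409
tsaE	RBF	modification	K06925
truA	RBF	modification	K06173
truB	RBF	modification	K03177
truD	RBF	modification	
trmA	RBF	modification	K00557
trmB	RBF	modification	K03439
trmD	RBF	modification	K00554
trmH	RBF	modification	
trmJ	RBF	modification	
trmL	RBF	modification	
miaA	RBF	modification	K00791
miaB	RBF	modification	K06168
mnmA	RBF	modification	K00566
mnmE	RBF	modification	K03650
mnmG	RBF	modification	K03495
tgt	RBF	modification	K00773
queA	RBF	modification	K07568
rplA	RP	other	K02863
rplB	RP	other	
rplC	RP	other	
rplD	RP	other	
rplE	RP	other	
rplF	RP	other	
rplI	RP	other	K02939
rplJ	RP	other	
rplK	RP	other	
rplL	RP	other	
rplM	RP	other	
rplN	RP	other	
rplO	RP	other	
rplP	RP	other	
rplQ	RP	other	
rplR	RP	other	
rplS	RP	other	
rplT	RP	other	
rplU	RP	other	
rplV	RP	other	
rplW	RP	other	
rplX	RP	other	
rplY	RP	other	
rpmA	RP	other	
rpmB	RP	other	
rpmC	RP	other	
rpmD	RP	other	
rpmE	RP	other	
rpmF	RP	other	
rpmG	RP	other	
rpmH	RP	other	
rpmI	RP	other	
rpmJ	RP	other	
rpsA	RP	other	
rpsB	RP	other	
rpsC	RP	other	
rpsD	RP	other	
rpsE	RP	other	
rpsF	RP	other	
rpsG	RP	other	
rpsH	RP	other	
rpsI	RP	other	
rpsJ	RP	other	
rpsK	RP	other	
rpsL	RP	other	
rpsM	RP	other	
rpsN	RP	other	
rpsO	RP	other	
rpsP	RP	other	
rpsQ	RP	other	
rpsR	RP	other	
rpsS	RP	other	
rpsT	RP	other	
rpsU	RP	other	
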