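region	fs_name	abbrev	hemi	lobe	class
bankssts_L	bankssts	BSTS_L	L	temporal	association
caudalanteriorcingulate_L	caudalanteriorcingulate	CAC_L	L	cingulate	paralimbic
caudalmiddlefrontal_L	caudalmiddlefrontal	CMF_L	L	frontal	association
cuneus_L	cuneus	CUN_L	L	occipital	association
entorhinal_L	entorhinal	ENT_L	L	temporal	association
frontalpole_L	frontalpole	FP_L	L	frontal	association
fusiform_L	fusiform	FUSI_L	L	temporal	association
inferiorparietal_L	inferiorparietal	IP_L	L	parietal	association
inferiortemporal_L	inferiortemporal	IT_L	L	temporal	association
insula_L	insula	INS_L	L	insula	paralimbic
isthmuscingulate_L	isthmuscingulate	ISTC_L	L	cingulate	paralimbic
lateraloccipital_L	lateraloccipital	LOCC_L	L	occipital	association
lateralorbitofrontal_L	lateralorbitofrontal	LOF_L	L	frontal	paralimbic
lingual_L	lingual	LING_L	L	occipital	association
medialorbitofrontal_L	medialorbitofrontal	MOF_L	L	frontal	paralimbic
middletemporal_L	middletemporal	MT_L	L	temporal	association
paracentral_L	paracentral	PARC_L	L	frontal	association
parahippocampal_L	parahippocampal	PARH_L	L	temporal	paralimbic
parsopercularis_L	parsopercularis	POPE_L	L	frontal	association
parsorbitalis_L	parsorbitalis	PORB_L	L	frontal	association
parstriangularis_L	parstriangularis	PTRI_L	L	frontal	association
pericalcarine_L	pericalcarine	PERI_L	L	occipital	primary
postcentral_L	postcentral	PSTC_L	L	parietal	primary
posteriorcingulate_L	posteriorcingulate	PC_L	L	cingulate	paralimbic
precentral_L	precentral	PREC_L	L	frontal	primary
precuneus_L	precuneus	PCUN_L	L	parietal	association
rostralanteriorcingulate_L	rostralanteriorcingulate	RAC_L	L	cingulate	paralimbic
rostralmiddlefrontal_L	rostralmiddlefrontal	RMF_L	L	frontal	association
superiorfrontal_L	superiorfrontal	SF_L	L	frontal	association
superiorparietal_L	superiorparietal	SP_L	L	parietal	association
superiortemporal_L	superiortemporal	ST_L	L	temporal	association
supramarginal_L	supramarginal	SMAR_L	L	parietal	association
temporalpole_L	temporalpole	TP_L	L	temporal	association
transversetemporal_L	transversetemporal	TT_L	L	temporal	primary
bankssts_R	bankssts	BSTS_R	R	temporal	association
caudalanteriorcingulate_R	caudalanteriorcingulate	CAC_R	R	cingulate	paralimbic
caudalmiddlefrontal_R	caudalmiddlefrontal	CMF_R	R	frontal	association
cuneus_R	cuneus	CUN_R	R	occipital	association
entorhinal_R	entorhinal	ENT_R	R	temporal	association
frontalpole_R	frontalpole	FP_R	R	frontal	association
fusiform_R	fusiform	FUSI_R	R	temporal	association
inferiorparietal_R	inferiorparietal	IP_R	R	parietal	association
inferiortemporal_R	inferiortemporal	IT_R	R	temporal	association
insula_R	insula	INS_R	R	insula	paralimbic
isthmuscingulate_R	isthmuscingulate	ISTC_R	R	cingulate	paralimbic
lateraloccipital_R	lateraloccipital	LOCC_R	R	occipital	association
lateralorbitofrontal_R	lateralorbitofrontal	LOF_R	R	frontal	paralimbic
lingual_R	lingual	LING_R	R	occipital	association
medialorbitofrontal_R	medialorbitofrontal	MOF_R	R	frontal	paralimbic
middletemporal_R	middletemporal	MT_R	R	temporal	association
paracentral_R	paracentral	PARC_R	R	frontal	association
parahippocampal_R	parahippocampal	PARH_R	R	temporal	paralimbic
parsopercularis_R	parsopercularis	POPE_R	R	frontal	association
parsorbitalis_R	parsorbitalis	PORB_R	R	frontal	association
parstriangularis_R	parstriangularis	PTRI_R	R	frontal	association
pericalcarine_R	pericalcarine	PERI_R	R	occipital	primary
postcentral_R	postcentral	PSTC_R	R	parietal	primary
posteriorcingulate_R	posteriorcingulate	PC_R	R	cingulate	paralimbic
precentral_R	precentral	PREC_R	R	frontal	primary
precuneus_R	precuneus	PCUN_R	R	parietal	association
rostralanteriorcingulate_R	rostralanteriorcingulate	RAC_R	R	cingulate	paralimbic
rostralmiddlefrontal_R	rostralmiddlefrontal	RMF_R	R	frontal	association
superiorfrontal_R	superiorfrontal	SF_R	R	frontal	association
superiorparietal_R	superiorparietal	SP_R	R	parietal	association
superiortemporal_R	superiortemporal	ST_R	R	temporal	association
supramarginal_R	supramarginal	SMAR_R	R	parietal	association
temporalpole_R	temporalpole	TP_R	R	temporal	association
transversetemporal_R	transversetemporal	TT_R	R	temporal	primary
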