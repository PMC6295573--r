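# Approximate MNI-like centroids for Desikan-Killiany cortical regions.
# SYNTHETIC stand-in coordinates for viewer export layout only; not measured
# from any surface reconstruction. Left hemisphere listed; right is mirrored
# in x by the loader.
region	x	y	z
bankssts_L	-54	-45	9
caudalanteriorcingulate_L	-5	20	30
caudalmiddlefrontal_L	-36	12	48
cuneus_L	-7	-80	27
entorhinal_L	-25	-8	-32
frontalpole_L	-9	62	-8
fusiform_L	-36	-45	-21
inferiorparietal_L	-42	-65	35
inferiortemporal_L	-50	-38	-24
insula_L	-36	-2	5
isthmuscingulate_L	-7	-45	25
lateraloccipital_L	-32	-87	3
lateralorbitofrontal_L	-26	32	-16
lingual_L	-15	-68	-5
medialorbitofrontal_L	-7	40	-17
middletemporal_L	-57	-30	-12
paracentral_L	-8	-27	57
parahippocampal_L	-26	-33	-18
parsopercularis_L	-47	14	15
parsorbitalis_L	-43	40	-10
parstriangularis_L	-46	32	5
pericalcarine_L	-12	-80	8
postcentral_L	-42	-25	47
posteriorcingulate_L	-6	-20	38
precentral_L	-38	-9	45
precuneus_L	-9	-58	40
rostralanteriorcingulate_L	-6	35	10
rostralmiddlefrontal_L	-32	42	22
superiorfrontal_L	-12	30	48
superiorparietal_L	-23	-58	55
superiortemporal_L	-55	-15	0
supramarginal_L	-52	-42	30
temporalpole_L	-32	12	-35
transversetemporal_L	-45	-22	8
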