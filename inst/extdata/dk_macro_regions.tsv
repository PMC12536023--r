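micro	hemisphere	lobe
caudalanteriorcingulate_left	left	cingulate
isthmuscingulate_left	left	cingulate
posteriorcingulate_left	left	cingulate
rostralanteriorcingulate_left	left	cingulate
caudalmiddlefrontal_left	left	frontal
frontalpole_left	left	frontal
lateralorbitofrontal_left	left	frontal
medialorbitofrontal_left	left	frontal
paracentral_left	left	frontal
parsopercularis_left	left	frontal
parsorbitalis_left	left	frontal
parstriangularis_left	left	frontal
precentral_left	left	frontal
rostralmiddlefrontal_left	left	frontal
superiorfrontal_left	left	frontal
cuneus_left	left	occipital
lateraloccipital_left	left	occipital
lingual_left	left	occipital
pericalcarine_left	left	occipital
inferiorparietal_left	left	parietal
postcentral_left	left	parietal
precuneus_left	left	parietal
superiorparietal_left	left	parietal
supramarginal_left	left	parietal
bankssts_left	left	temporal
entorhinal_left	left	temporal
fusiform_left	left	temporal
inferiortemporal_left	left	temporal
insula_left	left	temporal
middletemporal_left	left	temporal
parahippocampal_left	left	temporal
superiortemporal_left	left	temporal
temporalpole_left	left	temporal
transversetemporal_left	left	temporal
caudalanteriorcingulate_right	right	cingulate
isthmuscingulate_right	right	cingulate
posteriorcingulate_right	right	cingulate
rostralanteriorcingulate_right	right	cingulate
caudalmiddlefrontal_right	right	frontal
frontalpole_right	right	frontal
lateralorbitofrontal_right	right	frontal
medialorbitofrontal_right	right	frontal
paracentral_right	right	frontal
parsopercularis_right	right	frontal
parsorbitalis_right	right	frontal
parstriangularis_right	right	frontal
precentral_right	right	frontal
rostralmiddlefrontal_right	right	frontal
superiorfrontal_right	right	frontal
cuneus_right	right	occipital
lateraloccipital_right	right	occipital
lingual_right	right	occipital
pericalcarine_right	right	occipital
inferiorparietal_right	right	parietal
postcentral_right	right	parietal
precuneus_right	right	parietal
superiorparietal_right	right	parietal
supramarginal_right	right	parietal
bankssts_right	right	temporal
entorhinal_right	right	temporal
fusiform_right	right	temporal
inferiortemporal_right	right	temporal
insula_right	right	temporal
middletemporal_right	right	temporal
parahippocampal_right	right	temporal
superiortemporal_right	right	temporal
temporalpole_right	right	temporal
transversetemporal_right	right	temporal
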