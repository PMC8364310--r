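roi_name	hemisphere	off_target
bankssts	left	FALSE
caudalanteriorcingulate	left	FALSE
caudalmiddlefrontal	left	FALSE
cuneus	left	FALSE
entorhinal	left	FALSE
frontalpole	left	FALSE
fusiform	left	FALSE
inferiorparietal	left	FALSE
inferiortemporal	left	FALSE
insula	left	FALSE
isthmuscingulate	left	FALSE
lateraloccipital	left	FALSE
lateralorbitofrontal	left	FALSE
lingual	left	FALSE
medialorbitofrontal	left	FALSE
middletemporal	left	FALSE
paracentral	left	FALSE
parahippocampal	left	FALSE
parsopercularis	left	FALSE
parsorbitalis	left	FALSE
parstriangularis	left	FALSE
pericalcarine	left	FALSE
postcentral	left	FALSE
posteriorcingulate	left	FALSE
precentral	left	FALSE
precuneus	left	FALSE
rostralanteriorcingulate	left	FALSE
rostralmiddlefrontal	left	FALSE
superiorfrontal	left	FALSE
superiorparietal	left	FALSE
superiortemporal	left	FALSE
supramarginal	left	FALSE
temporalpole	left	FALSE
transversetemporal	left	FALSE
thalamus	left	TRUE
caudate	left	TRUE
putamen	left	TRUE
pallidum	left	TRUE
hippocampus	left	FALSE
amygdala	left	FALSE
accumbens	left	FALSE
ventraldc	left	FALSE
bankssts	right	FALSE
caudalanteriorcingulate	right	FALSE
caudalmiddlefrontal	right	FALSE
cuneus	right	FALSE
entorhinal	right	FALSE
frontalpole	right	FALSE
fusiform	right	FALSE
inferiorparietal	right	FALSE
inferiortemporal	right	FALSE
insula	right	FALSE
isthmuscingulate	right	FALSE
lateraloccipital	right	FALSE
lateralorbitofrontal	right	FALSE
lingual	right	FALSE
medialorbitofrontal	right	FALSE
middletemporal	right	FALSE
paracentral	right	FALSE
parahippocampal	right	FALSE
parsopercularis	right	FALSE
parsorbitalis	right	FALSE
parstriangularis	right	FALSE
pericalcarine	right	FALSE
postcentral	right	FALSE
posteriorcingulate	right	FALSE
precentral	right	FALSE
precuneus	right	FALSE
rostralanteriorcingulate	right	FALSE
rostralmiddlefrontal	right	FALSE
superiorfrontal	right	FALSE
superiorparietal	right	FALSE
superiortemporal	right	FALSE
supramarginal	right	FALSE
temporalpole	right	FALSE
transversetemporal	right	FALSE
thalamus	right	TRUE
caudate	right	TRUE
putamen	right	TRUE
pallidum	right	TRUE
hippocampus	right	FALSE
amygdala	right	FALSE
accumbens	right	FALSE
ventraldc	right	FALSE
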