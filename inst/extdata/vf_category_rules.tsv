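pattern	field	category
(haemophilus|pasteurell)\w*.{0,80}(iron|ferr\w*|sidero\w*|h(a)?em\w*|transferrin)	any	haemophilus_iron
(iron|ferr\w*|sidero\w*|h(a)?em\w*|transferrin).{0,80}(haemophilus|pasteurell)	any	haemophilus_iron
iron|ferric|ferrous|ferri\w*|ferrichrome|siderophore|h(a)?emin|h(a)?emoglobin|h(a)?eme?\b|h(a)?em-|transferrin|lactoferrin|enterobactin|aerobactin|tonb	any	iron_related
vibrio.{0,3}cholerae|v\.\s*cholerae|cholera|\bctx[ab]?\b|\btcp[a-s]\b|toxin.{0,2}coregulated	any	vibrio_cholerae
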