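# Unit tokens recognised by the dosage-stripping stage.
# A dosage token is NUMBER [space] UNIT; the unit must be followed by a
# non-alphanumeric character or end of string. One unit per line; '#' comments.
mg/ml
mcg/ml
mg/l
iu/ml
meq/ml
mg
mcg
ug
g
gm
kg
ml
dl
l
iu
meq
mmol
units
unit
%
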