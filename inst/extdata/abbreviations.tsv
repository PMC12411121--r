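abbrev	expansion
hcl	hydrochloride
hbr	hydrobromide
hctz	hydrochlorothiazide
vit	vitamin
sod	sodium
pot	potassium
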