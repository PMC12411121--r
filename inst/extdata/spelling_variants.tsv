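uk	us
sulphasalazine	sulfasalazine
sulphate	sulfate
sulphur	sulfur
sulphadiazine	sulfadiazine
aluminium	aluminum
oestrogen	estrogen
oestradiol	estradiol
anaesthetic	anesthetic
frusemide	furosemide
amoxycillin	amoxicillin
beclometasone	beclomethasone
ciclosporin	cyclosporine
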