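route_term	route_class
ORAL	ORAL
PO	ORAL
BY MOUTH	ORAL
PER ORAL	ORAL
OPHTHALMIC	OPHTHALMIC
OCULAR	OPHTHALMIC
INTRAOCULAR	OPHTHALMIC
TOPICAL	TOPICAL
CUTANEOUS	TOPICAL
TRANSDERMAL	TOPICAL
INTRAVENOUS	PARENTERAL
INTRAVENOUS DRIP	PARENTERAL
IV	PARENTERAL
INTRAMUSCULAR	PARENTERAL
IM	PARENTERAL
SUBCUTANEOUS	PARENTERAL
SC	PARENTERAL
PARENTERAL	PARENTERAL
INHALATION	INHALATION
RESPIRATORY (INHALATION)	INHALATION
NEBULIZATION	INHALATION
RECTAL	RECTAL
NASAL	NASAL
INTRANASAL	NASAL
VAGINAL	VAGINAL
SUBLINGUAL	OTHER
OTIC	OTHER
AURICULAR (OTIC)	OTHER
BUCCAL	OTHER
INTRATHECAL	OTHER
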