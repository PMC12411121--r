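dose_form	route_class
OPHTHALMIC SOLUTION	OPHTHALMIC
OPHTHALMIC OINTMENT	OPHTHALMIC
EYE DROPS	OPHTHALMIC
ORAL TABLET	ORAL
ORAL CAPSULE	ORAL
ORAL SOLUTION	ORAL
ORAL SUSPENSION	ORAL
TABLET	ORAL
CAPSULE	ORAL
SYRUP	ORAL
SUPPOSITORY	RECTAL
NASAL SPRAY	NASAL
CREAM	TOPICAL
OINTMENT	TOPICAL
TRANSDERMAL PATCH	TOPICAL
INJECTION	PARENTERAL
INJECTABLE SOLUTION	PARENTERAL
PREFILLED SYRINGE	PARENTERAL
METERED DOSE INHALER	INHALATION
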