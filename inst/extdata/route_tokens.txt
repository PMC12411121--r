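# Tokens removed by the route/dose-form stripping stage (whole tokens,
# case-insensitive). One token per line; '#' comments.
oral
orally
tablet
tablets
tab
capsule
capsules
cap
injection
injectable
intravenous
intramuscular
subcutaneous
topical
cutaneous
transdermal
ophthalmic
ocular
otic
nasal
intranasal
rectal
vaginal
sublingual
inhalation
inhaler
respiratory
cream
ointment
gel
lotion
solution
suspension
syrup
elixir
drops
drop
eye
ear
patch
spray
suppository
po
iv
im
sc
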