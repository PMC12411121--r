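# Tokens skipped by word-split matching. One per line; '#' comments.
and
the
for
with
of
in
or
plus
kit
pack
otc
nos
unknown
unspecified
drug
product
generic
brand
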