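# Canonical pigmentation / melanogenesis gene names (zebrafish-style symbols)
# used as the default colour-gene panel; matching is case-insensitive.
tyr
tyrp1
dct
slc7a11
mreg
ednrb1a
mitfa
pmela
oca2
slc24a5
slc45a2
kita
kitlga
mc1r
pax3a
sox10
tfec
gpr143
mlpha
rab27a
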