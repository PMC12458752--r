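# Default trigger lexicon for ConText-style modifier scoping.
# Format: pattern <TAB> modifier <TAB> direction <TAB> max_scope_chars
# Patterns are case-insensitive literals matched at word boundaries.
# Scope lengths are uniform within each modifier class and direction so that
# adding triggers can only add modifiers (monotonicity).
#
# ---- negated ----
no evidence of	negated	forward	120
no evidence for	negated	forward	120
no sign of	negated	forward	120
no signs of	negated	forward	120
no suspicious	negated	forward	120
no definite	negated	forward	120
no residual	negated	forward	120
no convincing	negated	forward	120
no	negated	forward	120
not	negated	forward	120
without	negated	forward	120
without evidence of	negated	forward	120
negative for	negated	forward	120
free of	negated	forward	120
absence of	negated	forward	120
clear of	negated	forward	120
rules out	negated	forward	120
ruled out	negated	forward	120
excludes	negated	forward	120
rather than	negated	forward	120
absent	negated	backward	60
not seen	negated	backward	60
not identified	negated	backward	60
is excluded	negated	backward	60
has resolved	negated	backward	60
# ---- historical ----
history of	historical	forward	120
past history of	historical	forward	120
known history of	historical	forward	120
previous	historical	forward	120
previously	historical	forward	120
prior	historical	forward	120
longstanding	historical	forward	120
status post	historical	forward	120
post resection of	historical	forward	120
treated in	historical	forward	120
resected in	historical	forward	120
diagnosed in	historical	forward	120
in the past	historical	backward	60
years ago	historical	backward	60
# ---- general / hypothetical ----
screening for	general	forward	120
surveillance for	general	forward	120
surveillance	general	forward	120
risk of	general	forward	120
risk for	general	forward	120
family history of	general	forward	120
in general	general	forward	120
protocol for	general	forward	120
guideline for	general	forward	120
counselled about	general	forward	120
discussed at	general	forward	120
to exclude	general	forward	120
query	general	forward	120
# ---- non-definite ----
possible	nondefinite	forward	120
possibly	nondefinite	forward	120
probable	nondefinite	forward	120
likely	nondefinite	forward	120
suspicious for	nondefinite	forward	120
suspicion of	nondefinite	forward	120
suspected	nondefinite	forward	120
cannot exclude	nondefinite	forward	120
cannot rule out	nondefinite	forward	120
may represent	nondefinite	forward	120
could represent	nondefinite	forward	120
concerning for	nondefinite	forward	120
suggestive of	nondefinite	forward	120
equivocal for	nondefinite	forward	120
differential includes	nondefinite	forward	120
versus	nondefinite	forward	120
indeterminate	nondefinite	backward	60
is uncertain	nondefinite	backward	60
# ---- metastasis ----
metastasis	metastasis	bidirectional	120
metastases	metastasis	bidirectional	120
metastatic	metastasis	bidirectional	120
mets	metastasis	bidirectional	120
secondary deposit	metastasis	bidirectional	120
secondary deposits	metastasis	bidirectional	120
secondaries	metastasis	bidirectional	120
distant spread	metastasis	bidirectional	120
disseminated	metastasis	bidirectional	120
spread to	metastasis	forward	120
deposit in	metastasis	forward	120
# ---- recurrence ----
recurrence	recurrence	bidirectional	120
recurrent	recurrence	forward	120
recurred	recurrence	backward	60
relapse	recurrence	bidirectional	120
relapsed	recurrence	backward	60
regrowth	recurrence	bidirectional	120
re-growth	recurrence	bidirectional	120
local recurrence	recurrence	bidirectional	120
# ---- treatment response ----
response to treatment	treatment_response	bidirectional	120
treatment response	treatment_response	bidirectional	120
response to chemotherapy	treatment_response	bidirectional	120
response to chemoradiotherapy	treatment_response	bidirectional	120
responding to	treatment_response	forward	120
post-treatment change	treatment_response	bidirectional	120
regression of	treatment_response	forward	120
has regressed	treatment_response	backward	60
shrinkage of	treatment_response	forward	120
reduced in size	treatment_response	backward	60
interval decrease in	treatment_response	forward	120
downstaged	treatment_response	backward	60
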