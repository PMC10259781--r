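# Antipsychotic generic names used for the polypharmacy covariate.
# Editable: the set of approved antipsychotics changes over time, so this
# list is configuration, not code.
chlorpromazine
levomepromazine
fluphenazine
perphenazine
propericiazine
haloperidol
bromperidol
timiperone
spiperone
pimozide
sulpiride
sultopride
nemonapride
mosapramine
clocapramine
zotepine
oxypertine
risperidone
paliperidone
perospirone
blonanserin
olanzapine
quetiapine
aripiprazole
brexpiprazole
asenapine
lurasidone
clozapine
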