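# Antiepileptic agents counted for the concomitant-antiepileptic covariate:
# valproate, carbamazepine, lamotrigine, clonazepam, diazepam (common
# spelling variants of valproate included).
valproate sodium
sodium valproate
valproate
valproic acid
carbamazepine
lamotrigine
clonazepam
diazepam
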