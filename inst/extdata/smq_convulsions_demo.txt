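# Demonstration convulsions term list (synthetic subset).
# A small set of seizure-related MedDRA-style preferred terms used by the
# examples, tests and the simulator. It is NOT the licensed SMQ term list:
# the full narrow-scope convulsions query (SMQ 20000079, 101 preferred
# terms) must be supplied by the user from their MedDRA distribution.
code: 20000079
scope: narrow
name: Convulsions (demo subset)
Seizure
Generalised tonic-clonic seizure
Status epilepticus
Epilepsy
Tonic convulsion
Clonic convulsion
Myoclonic epilepsy
Partial seizures
Atonic seizures
Seizure cluster
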