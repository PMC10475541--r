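name	group
Greater than 2 episodes	episode count
Greater than 5 episodes	episode count
Unilateral	laterality
Severe	pain intensity
Moderate to severe	pain intensity
More than 3 months	chronicity
Conjunctival injection	cranial autonomic
Eyelid edema	cranial autonomic
Forehead and facial sweating	cranial autonomic
Lacrimation	cranial autonomic
Miosis	cranial autonomic
Nasal congestion	cranial autonomic
Ptosis	cranial autonomic
Rhinorrhea	cranial autonomic
Restless	cranial autonomic
Orbital or supraorbital or temporal pain	pain site
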