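a	b
1 min to 24 h with severe intensity	Constant
1 min to 24 h with severe intensity	Unremitting within 24 h
1 min to 24 h with severe intensity	Up to 72 h with mild intensity
1 min to 24 h with severe intensity	Up to few seconds
1 to 14 days per month	Constant
1 to 14 days per month	Every other day to 8 per day
1 to 14 days per month	Greater than 1 per day
1 to 14 days per month	Greater than 15 days per month
1 to 14 days per month	Greater than 5 per day
1 to 14 days per month	Less than 12 days per year
1 to 14 days per month	More than 1 episode per day
1 to 14 days per month	Unremitting within 24 h
1 to 600 s	15 min up to 4 h after waking
1 to 600 s	15 to 180 min
1 to 600 s	30 min to 7 days in duration
1 to 600 s	4 to 72 h
1 to 600 s	Greater than 5 min
1 to 600 s	Constant
1 to 600 s	Hours to days
1 to 600 s	Unremitting within 24 h
15 min up to 4 h after waking	4 to 72 h
15 min up to 4 h after waking	Constant
15 min up to 4 h after waking	Unremitting within 24 h
15 min up to 4 h after waking	Up to few seconds
15 to 180 min	4 to 72 h
15 to 180 min	Constant
15 to 180 min	Unremitting within 24 h
15 to 180 min	Up to few seconds
2 to 30 min	4 to 72 h
2 to 30 min	Constant
2 to 30 min	Hours to days
2 to 30 min	Unremitting within 24 h
2 to 30 min	Up to few seconds
30 min to 7 days in duration	Constant
30 min to 7 days in duration	Unremitting within 24 h
30 min to 7 days in duration	Up to few seconds
4 to 72 h	Between 1 s to 2 h
4 to 72 h	Constant
4 to 72 h	Unremitting within 24 h
4 to 72 h	Up to few seconds
Abrupt explosive intensity just before or with orgasm	Increasing in intensity with increasing sexual excitement
Aggravated by physical activity	Restless
Aggravated by physical activity	Not aggrevated by activity
Between 1 s to 2 h	Constant
Between 1 s to 2 h	Unremitting within 24 h
Bilateral location	Unilateral
Brought on by exercise	Restless
Conjunctival injection	No conjunctival injection
Constant	Developing only during sleep and causing wakening
Constant	Each individual aura symptom lasts 5–60 min
Constant	Every other day to 8 per day
Constant	Fully reversible
Constant	Hours to days
Constant	Irregular frequency
Constant	Less than 12 days per year
Constant	Less than 48 h
Constant	Resolve within 1 h after removal of compression
Constant	Resolve within 1 h after removal of traction
Constant	Resolve within 30 min after removal of cold
Constant	Up to 72 h with mild intensity
Constant	Up to few seconds
Every other day to 8 per day	Unremitting within 24 h
Every other day to 8 per day	Constant
Eyelid edema	No eyelid edema
Forehead and facial sweating	No forehead and facial sweating
Fully reversible	Unremitting within 24 h
Greater than 15 days per month	Less than 12 days per year
Greater than 8 days per month	Less than 12 days per year
Hours to days	Resolve within 1 h after removal of compression
Hours to days	Resolve within 1 h after removal of traction
Hours to days	Resolve within 30 min after removal of cold
Hours to days	Unremitting within 24 h
Hours to days	Up to few seconds
Hours to days	Constant
Irregular frequency	Unremitting within 24 h
Irregular frequency	Constant
Lacrimation	No lacrimation
Less than 12 days per year	More than 10 days per month
Less than 12 days per year	Unremitting within 24 h
Less than 12 days per year	Constant
Less than 48 h	Unremitting within 24 h
Less than 48 h	Constant
Mild to moderate pain	Severe
Miosis	No miosis
Moderate to severe	Up to 72 h with mild intensity
More than 1 episode per day	Unremitting within 24 h
More than 1 episode per day	Constant
Nasal congestion	No nasal congestion
Nausea/vomiting	No nausea/vomiting
No orbital or supraorbital or temporal pain	Orbital or supraorbital or temporal pain
No phonophobia	Phonophobia
No photophobia	Photophobia
No ptosis	Ptosis
No restless	Restless
No rhinorrhea	Rhinorrhea
Nonpulsating	Pulsating
Severe	Up to 72 h with mild intensity
Unremitting within 24 h	Up to 72 h with mild intensity
Unremitting within 24 h	Up to few seconds
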