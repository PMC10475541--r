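a	b	rationale
4 to 72 h	The aura is accompanied or followed within 60 min by headache	both describe the headache phase of a migraine attack; the aura-associated headache falls inside the 4-72 h window
15 to 180 min	Hours to days	duration ranges intersect (attacks of a few hours satisfy both)
15 to 180 min	30 min to 7 days in duration	duration ranges intersect (30-180 min satisfies both)
2 to 30 min	30 min to 7 days in duration	duration ranges touch at 30 min
1 to 600 s	Up to few seconds	duration ranges intersect (attacks of a few seconds satisfy both)
1 to 600 s	1 min to 24 h with severe intensity	duration ranges intersect (1-10 min satisfies both)
Clearly remembered onset	Max within 1 min	onset reaching maximum within a minute is by nature clearly remembered
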