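diagnosis_a	diagnosis_b	rationale
3.4	4.8	both are strictly side-locked headaches confined to a fixed area
4.10	4.8	both present as a fixed, persistent headache phenotype (side-locked NDPH overlaps the coin-shaped fixed-area phenotype)
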