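SET_ALPHA	first set	G1	G2	G3
SET_BETA	second set	G2	G4
SET_GAMMA	third set	G5	G6	G7	G8
SET_DELTA	fourth set	G1
SET_EPSILON	fifth set	G9	G10	G2	G4	G6
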