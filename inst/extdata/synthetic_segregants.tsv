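MARKER	POS	K_SUPERIOR	M_SCORED
S1	10000	19	20
S2	20000	18	20
S3	30000	20	20
S4	40000	17	20
S5	50000	11	20
S6	60000	9	20
S7	70000	10	20
S8	80000	12	20
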