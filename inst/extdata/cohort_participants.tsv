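cohort	White	Other	Asian	Black	Male	Female
HMP	39	2	7	2	30	20
GW	24	0	6	18	21	27
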