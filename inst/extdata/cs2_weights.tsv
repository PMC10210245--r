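trajectory_id	label	weight_pct
cs2_t1	triplet	44.7
cs2_t2	bound	17.8
cs2_t3	singlet	10.4
cs2_t4	bound	10.2
cs2_t5	triplet	7.42
cs2_t6	singlet	4.42
cs2_t7	triplet	3.39
cs2_t8	singlet	1.67
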