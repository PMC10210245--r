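trajectory_id	label	weight_pct
chd_t1	open (indirect)	28.4
chd_t2	closed	27.3
chd_t3	closed	15.1
chd_t4	closed	9.70
chd_t5	open	8.70
chd_t6	open (indirect)	6.05
chd_t7	open	3.38
chd_t8	open	1.35
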