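protein_id	TOY_untreated_bio_1	TOY_untreated_bio_2	TOY_untreated_bio_3	TOY_untreated_ctrl_1	TOY_untreated_ctrl_2	TOY_untreated_ctrl_3	TOY_stress_bio_1	TOY_stress_bio_2	TOY_stress_bio_3	TOY_stress_ctrl_1	TOY_stress_ctrl_2	TOY_stress_ctrl_3	TOY_untreated_bio_1.peptides	TOY_untreated_bio_2.peptides	TOY_untreated_bio_3.peptides	TOY_untreated_ctrl_1.peptides	TOY_untreated_ctrl_2.peptides	TOY_untreated_ctrl_3.peptides	TOY_stress_bio_1.peptides	TOY_stress_bio_2.peptides	TOY_stress_bio_3.peptides	TOY_stress_ctrl_1.peptides	TOY_stress_ctrl_2.peptides	TOY_stress_ctrl_3.peptides
P1	100	120	110	10	10	10	300	280	320	10	10	10	5	5	5	2	2	2	5	5	5	2	2	2
P2	50	60	0	5	5	5	80	0	90	5	5	5	3	3	0	1	1	1	3	0	3	1	1	1
P3	1000	900	950	1	1	1	20	30	25	1	1	1	4	4	4	1	1	1	4	4	4	1	1	1
P4	200	210	190	10	10	10	205	195	200	10	10	10	1	1	1	1	1	1	1	1	1	1	1	1
P5	90	100	110	40	50	60	90	100	110	40	50	60	4	4	4	2	2	2	4	4	4	2	2	2
P6	500	0	0	0	0	0	0	600	0	0	0	0	4	0	0	0	0	0	0	5	0	0	0	0
P7	300	300	300	10	10	10	60	70	50	30	25	35	3	3	3	1	1	1	3	3	3	1	1	1
P8	40	45	50	8	8	8	55	60	42	8	8	8	1	1	1	3	3	3	1	1	1	3	3	3
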