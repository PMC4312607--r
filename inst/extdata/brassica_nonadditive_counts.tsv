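amphidiploid	parent1	parent2	dominance	above	below
Bn	Br	Bo	p1_gt_p2	5220	4299
Bn	Br	Bo	p1_lt_p2	4385	5940
Bj	Br	Bg	p1_gt_p2	6429	4744
Bj	Br	Bg	p1_lt_p2	3811	5333
Bc	Bg	Bo	p1_gt_p2	3399	5790
Bc	Bg	Bo	p1_lt_p2	4591	6141
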