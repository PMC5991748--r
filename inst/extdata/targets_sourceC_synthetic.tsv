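mirna	gene	score
miR-275	GENE004	0.512
miR-275	GENE008	0.975
miR-275	GENE010	0.764
miR-275	GENE013	0.573
miR-275	GENE019	0.772
miR-275	GENE021	0.514
miR-275	GENE025	0.764
miR-275	GENE026	0.989
miR-275	GENE035	0.932
miR-275	GENE038	0.848
miR-276	GENE005	0.766
miR-276	GENE012	0.89
miR-276	GENE016	0.665
miR-276	GENE018	0.612
miR-276	GENE024	0.906
miR-276	GENE025	0.992
miR-276	GENE035	0.926
miR-277	GENE004	0.678
miR-277	GENE007	0.514
miR-277	GENE009	0.514
miR-277	GENE014	0.64
miR-277	GENE018	0.63
miR-277	GENE019	0.846
miR-277	GENE020	0.978
miR-277	GENE024	0.724
miR-277	GENE030	0.969
miR-277	GENE033	0.994
miR-277	GENE035	0.978
miR-277	GENE040	0.682
miR-278	GENE003	0.602
miR-278	GENE004	0.812
miR-278	GENE005	0.95
miR-278	GENE006	0.92
miR-278	GENE008	0.74
miR-278	GENE009	0.826
miR-278	GENE012	0.9
miR-278	GENE013	0.542
miR-278	GENE016	0.83
miR-278	GENE017	0.955
miR-278	GENE019	0.891
miR-278	GENE023	0.875
miR-278	GENE027	0.739
miR-278	GENE028	0.589
miR-278	GENE032	0.895
miR-278	GENE037	0.666
miR-278	GENE038	0.9
miR-278	GENE039	0.986
miR-278	GENE040	0.698
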