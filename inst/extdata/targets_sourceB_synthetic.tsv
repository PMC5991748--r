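mirna	gene	score
miR-275	GENE004	0.958
miR-275	GENE010	0.748
miR-275	GENE011	0.583
miR-275	GENE015	0.701
miR-275	GENE016	0.639
miR-275	GENE018	0.568
miR-275	GENE021	0.715
miR-275	GENE022	0.775
miR-275	GENE026	0.853
miR-275	GENE030	0.993
miR-276	GENE005	0.616
miR-276	GENE007	0.617
miR-276	GENE011	0.742
miR-276	GENE013	0.795
miR-276	GENE016	0.631
miR-276	GENE026	0.502
miR-276	GENE038	0.709
miR-277	GENE004	0.975
miR-277	GENE007	0.827
miR-277	GENE011	0.87
miR-277	GENE014	0.728
miR-277	GENE020	0.935
miR-277	GENE024	0.976
miR-277	GENE025	0.84
miR-277	GENE027	0.78
miR-277	GENE028	0.699
miR-277	GENE032	0.697
miR-277	GENE033	0.741
miR-277	GENE035	0.7
miR-278	GENE003	0.67
miR-278	GENE004	0.526
miR-278	GENE005	0.5
miR-278	GENE006	0.576
miR-278	GENE007	0.551
miR-278	GENE008	0.682
miR-278	GENE009	0.513
miR-278	GENE011	0.937
miR-278	GENE012	0.807
miR-278	GENE016	0.574
miR-278	GENE019	0.626
miR-278	GENE022	0.674
miR-278	GENE027	0.682
miR-278	GENE028	0.561
miR-278	GENE032	0.924
miR-278	GENE037	0.997
miR-278	GENE038	0.733
miR-278	GENE039	0.742
miR-278	GENE040	0.543
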