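mirna	gene	score
miR-275	GENE003	0.929
miR-275	GENE004	0.645
miR-275	GENE005	0.572
miR-275	GENE010	0.559
miR-275	GENE017	0.654
miR-275	GENE020	0.908
miR-275	GENE021	0.59
miR-275	GENE026	0.791
miR-275	GENE030	0.819
miR-275	GENE040	0.686
miR-276	GENE004	0.84
miR-276	GENE005	0.714
miR-276	GENE006	0.657
miR-276	GENE015	0.793
miR-276	GENE033	0.727
miR-276	GENE037	0.65
miR-276	GENE038	0.897
miR-277	GENE004	0.672
miR-277	GENE007	0.724
miR-277	GENE008	0.804
miR-277	GENE014	0.537
miR-277	GENE019	0.756
miR-277	GENE020	0.582
miR-277	GENE023	0.671
miR-277	GENE024	0.967
miR-277	GENE033	0.711
miR-277	GENE034	0.981
miR-277	GENE035	0.539
miR-277	GENE040	0.779
miR-278	GENE003	0.748
miR-278	GENE004	0.898
miR-278	GENE005	0.534
miR-278	GENE006	0.547
miR-278	GENE008	0.635
miR-278	GENE016	0.849
miR-278	GENE017	0.532
miR-278	GENE018	0.866
miR-278	GENE019	0.655
miR-278	GENE027	0.789
miR-278	GENE028	0.841
miR-278	GENE029	0.723
miR-278	GENE032	0.858
miR-278	GENE033	0.944
miR-278	GENE036	0.674
miR-278	GENE037	0.97
miR-278	GENE038	0.678
miR-278	GENE039	0.805
miR-278	GENE040	0.747
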