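TERM001	focal adhesion	GENE026	GENE006	GENE011	GENE038	GENE009	GENE002	GENE010	GENE030	GENE034	GENE020	GENE027	GENE031
TERM002	viral carcinogenesis	GENE031	GENE023	GENE010	GENE036	GENE037	GENE009	GENE002	GENE001	GENE007	GENE017
TERM003	cytoplasm	GENE009	GENE028	GENE013	GENE014	GENE002	GENE017	GENE037	GENE019	GENE016	GENE025	GENE033	GENE011	GENE040	GENE018	GENE034	GENE005	GENE036	GENE012	GENE015	GENE030
TERM004	cell cycle	GENE034	GENE027	GENE033	GENE009	GENE035	GENE010	GENE040	GENE038
TERM005	apoptosis	GENE002	GENE029	GENE012	GENE001	GENE010	GENE038	GENE036	GENE031	GENE008
TERM006	signal transduction	GENE036	GENE004	GENE021	GENE034	GENE037	GENE031	GENE007	GENE039	GENE016	GENE040	GENE009	GENE002	GENE025	GENE033	GENE017
TERM007	adherens junction	GENE016	GENE019	GENE008	GENE014	GENE007	GENE037	GENE038	GENE035	GENE004	GENE099
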