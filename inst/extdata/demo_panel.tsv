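#trait_id=demo_trait
#mode=TOP_SNP
#provenance=simulated (beta_sd=0.15, fst=0, seed=99)
rsid	effect_allele	other_allele	beta	freq_AFR	freq_AMR	freq_EAS	freq_EUR	freq_SAS
rs0000001	G	A	-0.129576778221727	0.576240666396916	0.576240666396916	0.576240666396916	0.576240666396916	0.576240666396916
rs0000002	C	T	0.0734436400038553	0.152403507707641	0.152403507707641	0.152403507707641	0.152403507707641	0.152403507707641
rs0000003	G	T	-0.0546175368819994	0.665838269330561	0.665838269330561	0.665838269330561	0.665838269330561	0.665838269330561
rs0000004	A	C	-0.194136301002288	0.943257899465971	0.943257899465971	0.943257899465971	0.943257899465971	0.943257899465971
rs0000005	C	A	-0.111865356814293	0.531494226050563	0.531494226050563	0.531494226050563	0.531494226050563	0.531494226050563
rs0000006	G	A	0.138232554300848	0.919952657655813	0.919952657655813	0.919952657655813	0.919952657655813	0.919952657655813
rs0000007	C	A	0.112508152560189	0.654284804244526	0.654284804244526	0.654284804244526	0.654284804244526	0.654284804244526
rs0000008	T	C	-0.37628310238375	0.315119940973818	0.315119940973818	0.315119940973818	0.315119940973818	0.315119940973818
rs0000009	C	T	-0.456140114301663	0.372526686149649	0.372526686149649	0.372526686149649	0.372526686149649	0.372526686149649
rs0000010	A	C	3.98700813880759e-05	0.207783277775161	0.207783277775161	0.207783277775161	0.207783277775161	0.207783277775161
rs0000011	G	T	-0.0591028491344033	0.543935647537	0.543935647537	0.543935647537	0.543935647537	0.543935647537
rs0000012	A	G	-0.261754149116701	0.504906532680616	0.504906532680616	0.504906532680616	0.504906532680616	0.504906532680616
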