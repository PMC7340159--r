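rsid	chromosome	position	ref	alt	freq_AFR	freq_AMR	freq_EAS	freq_EUR	freq_SAS
rs0000001	1	11000	A	G	0.576240666396916	0.576240666396916	0.576240666396916	0.576240666396916	0.576240666396916
rs0000002	2	12000	T	C	0.152403507707641	0.152403507707641	0.152403507707641	0.152403507707641	0.152403507707641
rs0000003	3	13000	T	G	0.665838269330561	0.665838269330561	0.665838269330561	0.665838269330561	0.665838269330561
rs0000004	4	14000	C	A	0.943257899465971	0.943257899465971	0.943257899465971	0.943257899465971	0.943257899465971
rs0000005	5	15000	A	C	0.531494226050563	0.531494226050563	0.531494226050563	0.531494226050563	0.531494226050563
rs0000006	6	16000	A	G	0.919952657655813	0.919952657655813	0.919952657655813	0.919952657655813	0.919952657655813
rs0000007	7	17000	A	C	0.654284804244526	0.654284804244526	0.654284804244526	0.654284804244526	0.654284804244526
rs0000008	8	18000	C	T	0.315119940973818	0.315119940973818	0.315119940973818	0.315119940973818	0.315119940973818
rs0000009	9	19000	T	C	0.372526686149649	0.372526686149649	0.372526686149649	0.372526686149649	0.372526686149649
rs0000010	10	20000	C	A	0.207783277775161	0.207783277775161	0.207783277775161	0.207783277775161	0.207783277775161
rs0000011	11	21000	T	G	0.543935647537	0.543935647537	0.543935647537	0.543935647537	0.543935647537
rs0000012	12	22000	G	A	0.504906532680616	0.504906532680616	0.504906532680616	0.504906532680616	0.504906532680616
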