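# This data file was generated by a consumer genotyping service.
# rsid	chromosome	position	genotype
rs0000001	1	11000	GG
rs0000002	2	12000	TT
rs0000003	3	13000	GT
rs0000004	4	14000	AA
rs0000005	5	15000	--
rs0000006	6	16000	GG
rs0000007	7	17000	CA
rs0000008	8	18000	CC
rs0000009	9	19000	CT
rs0000010	10	20000	CC
rs0000011	11	21000	GT
rs0000012	12	22000	GG
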