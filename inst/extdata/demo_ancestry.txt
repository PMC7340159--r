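rsid	chromosome	position	allele1	allele2
rs0000001	1	11000	G	G
rs0000002	2	12000	T	T
rs0000003	3	13000	G	T
rs0000004	4	14000	A	A
rs0000005	5	15000	0	0
rs0000006	6	16000	G	G
rs0000007	7	17000	C	A
rs0000008	8	18000	C	C
rs0000009	9	19000	C	T
rs0000010	10	20000	C	C
rs0000011	11	21000	G	T
rs0000012	12	22000	G	G
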