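population	n_ind	n_samples	n_tissues	single_total	multi_total	single_gt	multi_gt	single_maf	multi_maf
RJFh	36	72	3	1050035	2604288	265750	578726	152029	319268
Cobb	48	96	2	3771992	5464266	949127	1678364	558020	952445
FLLL	32	64	2	1729800	2033207	535228	1109324	368280	714523
HerX	23	23	1	1332709	1332709	481314	481314	307859	307859
Novo1	32	32	1	1459352	1459352	447594	447594	264804	264804
Novo2	44	104	2	1289199	2146975	390195	738109	243892	449446
RpRm	112	286	5	1841778	4032988	555928	1279458	307049	631868
Rmx6	19	19	1	NA	2123217	NA	715822	NA	483379
FrAg	4	7	2	1247253	1732440	784397	1055772	520277	583742
Lsnu	16	32	2	1487176	2284902	590399	836800	384720	534938
Fayo	16	32	2	1320244	2033207	496412	698932	288464	396446
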