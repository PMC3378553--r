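symbol	role	clusters
RAB1A	rab	RAB1
RAB1B	rab	RAB1
RAB2A	rab	RAB2
RAB2B	rab	RAB2
RAB3A	rab	RAB3
RAB3B	rab	RAB3
RAB3C	rab	RAB3
RAB3D	rab	RAB3
RAB4A	rab	RAB4
RAB4B	rab	RAB4
RAB5A	rab	RAB5
RAB5B	rab	RAB5
RAB5C	rab	RAB5
RAB6A	rab	RAB6
RAB6B	rab	RAB6
RAB6C	rab	RAB6
RAB7A	rab	RAB7
RAB7B	rab	RAB7
RAB8A	rab	RAB8
RAB8B	rab	RAB8
RAB9A	rab	RAB9
RAB9B	rab	RAB9
RAB10	rab	RAB10
RAB11A	rab	RAB11
RAB11B	rab	RAB11
RAB12	rab	RAB12
RAB13	rab	RAB13
RAB14	rab	RAB14
RAB15	rab	RAB15
RAB17	rab	RAB17
RAB18	rab	RAB18
RAB19	rab	RAB19
RAB20	rab	RAB20
RAB21	rab	RAB21
RAB22A	rab	RAB22
RAB23	rab	RAB23
RAB24	rab	RAB24
RAB25	rab	RAB25
RAB26	rab	RAB26
RAB27A	rab	RAB27
RAB27B	rab	RAB27
RAB28	rab	RAB28
RAB30	rab	RAB30
RAB31	rab	RAB31
RAB32	rab	RAB32
RAB33A	rab	RAB33
RAB33B	rab	RAB33
RAB34	rab	RAB34
RAB35	rab	RAB35
RAB36	rab	RAB36
RAB37	rab	RAB37
RAB38	rab	RAB38
RAB39A	rab	RAB39
RAB39B	rab	RAB39
RAB40A	rab	RAB40
RAB40B	rab	RAB40
RAB40C	rab	RAB40
RAB41	rab	RAB41
RAB42	rab	RAB42
RAB43	rab	RAB43
RAB44	rab	RAB44
TRAPPC1	gef	RAB1
MADD	gef	RAB27;RAB3
RIN1	gef	RAB5
CCZ1	gef	RAB7
ANKRD27	gef	RAB21
SYNGEF001	gef	RAB1;RAB21
SYNGEF002	gef	RAB1;RAB22
SYNGEF003	gef	RAB1;RAB31
SYNGEF004	gef	RAB1;RAB35
SYNGEF005	gef	RAB1;RAB35
SYNGEF006	gef	RAB1;RAB35
SYNGEF007	gef	RAB1
SYNGEF008	gef	RAB3
SYNGEF009	gef	RAB3
SYNGEF010	gef	RAB5
SYNGEF011	gef	RAB5
SYNGEF012	gef	RAB5
SYNGEF013	gef	RAB5
SYNGEF014	gef	RAB5
SYNGEF015	gef	RAB5
SYNGEF016	gef	RAB8
SYNGEF017	gef	RAB8
SYNGEF018	gef	RAB10
TBC1D10A	gap	RAB27
TBC1D3B	gap	RAB5
TBC1D30	gap	RAB8
TBC1D4	gap	RAB10
RABGAP1L	gap	RAB22
SYNGAP001	gap	RAB1;RAB7;RAB39
SYNGAP002	gap	RAB2;RAB8;RAB41
SYNGAP003	gap	RAB2;RAB10;RAB43
SYNGAP004	gap	RAB2;RAB10
SYNGAP005	gap	RAB3;RAB11
SYNGAP006	gap	RAB3;RAB11
SYNGAP007	gap	RAB3;RAB11
SYNGAP008	gap	RAB4;RAB14
SYNGAP009	gap	RAB4;RAB17
SYNGAP010	gap	RAB5;RAB21
SYNGAP011	gap	RAB5;RAB22
SYNGAP012	gap	RAB5;RAB23
SYNGAP013	gap	RAB5;RAB34
SYNGAP014	gap	RAB6;RAB35
SYNGAP015	gap	RAB6;RAB36
MICAL1	effector	RAB1
MICAL2	effector	RAB1
LEPRE1	effector	RAB1
ICA1	effector	RAB2
GMCL1	effector	RAB2
STXBP1	effector	RAB3
UNC13B	effector	RAB3
TMEM22	effector	RAB3
ZWINT	effector	RAB3
GNAL	effector	RAB3
CD2AP	effector	RAB4
EEA1	effector	RAB5
F8A1	effector	RAB5
CAV1	effector	RAB5
SDC1	effector	RAB5
YWHAQ	effector	RAB5
KIF20A	effector	RAB6
GCC2	effector	RAB6;RAB27
MYO5C	effector	RAB8
RABAC1	effector	RAB8
RAB11FIP1	effector	RAB11;RAB25
RAB11FIP2	effector	RAB11
MYO5B	effector	RAB11
PIGR	effector	RAB11
REP15	effector	RAB15
ITGA5	effector	RAB25
EXPH5	effector	RAB27
MLPH	effector	RAB27
MYRIP	effector	RAB27
RPH3A	effector	RAB27
RPH3AL	effector	RAB27
SYTL1	effector	RAB27
SYTL2	effector	RAB27
SYTL3	effector	RAB27
SYTL4	effector	RAB27
SYTL5	effector	RAB27
UNC13D	effector	RAB27
CASP1	effector	RAB39
SYNEFF001	effector	RAB1;RAB9
SYNEFF002	effector	RAB1;RAB9
SYNEFF003	effector	RAB1;RAB9
SYNEFF004	effector	RAB1;RAB9
SYNEFF005	effector	RAB1;RAB9
SYNEFF006	effector	RAB1;RAB9
SYNEFF007	effector	RAB1;RAB9
SYNEFF008	effector	RAB1;RAB10
SYNEFF009	effector	RAB1;RAB10
SYNEFF010	effector	RAB1;RAB10
SYNEFF011	effector	RAB1;RAB10
SYNEFF012	effector	RAB1;RAB10
SYNEFF013	effector	RAB1;RAB10
SYNEFF014	effector	RAB1;RAB10
SYNEFF015	effector	RAB1;RAB10
SYNEFF016	effector	RAB2;RAB10
SYNEFF017	effector	RAB2;RAB11
SYNEFF018	effector	RAB2;RAB11
SYNEFF019	effector	RAB2;RAB11
SYNEFF020	effector	RAB3;RAB11
SYNEFF021	effector	RAB3;RAB11
SYNEFF022	effector	RAB3;RAB11
SYNEFF023	effector	RAB3;RAB11
SYNEFF024	effector	RAB3;RAB11
SYNEFF025	effector	RAB3;RAB11
SYNEFF026	effector	RAB3;RAB11
SYNEFF027	effector	RAB3;RAB11
SYNEFF028	effector	RAB3;RAB11
SYNEFF029	effector	RAB3;RAB11
SYNEFF030	effector	RAB3;RAB11
SYNEFF031	effector	RAB3;RAB11
SYNEFF032	effector	RAB3;RAB11
SYNEFF033	effector	RAB3;RAB11
SYNEFF034	effector	RAB3;RAB11
SYNEFF035	effector	RAB3;RAB11
SYNEFF036	effector	RAB3;RAB11
SYNEFF037	effector	RAB3;RAB11
SYNEFF038	effector	RAB4;RAB11
SYNEFF039	effector	RAB4;RAB11
SYNEFF040	effector	RAB4;RAB11
SYNEFF041	effector	RAB4;RAB11
SYNEFF042	effector	RAB4;RAB12
SYNEFF043	effector	RAB4;RAB13
SYNEFF044	effector	RAB4;RAB13
SYNEFF045	effector	RAB4;RAB13
SYNEFF046	effector	RAB4;RAB13
SYNEFF047	effector	RAB4;RAB13
SYNEFF048	effector	RAB4;RAB13
SYNEFF049	effector	RAB4;RAB13
SYNEFF050	effector	RAB4;RAB13
SYNEFF051	effector	RAB4;RAB13
SYNEFF052	effector	RAB4;RAB13
SYNEFF053	effector	RAB4;RAB14
SYNEFF054	effector	RAB4;RAB14
SYNEFF055	effector	RAB4;RAB14
SYNEFF056	effector	RAB5;RAB14
SYNEFF057	effector	RAB5;RAB14
SYNEFF058	effector	RAB5;RAB15
SYNEFF059	effector	RAB5;RAB15
SYNEFF060	effector	RAB5;RAB15
SYNEFF061	effector	RAB5;RAB15
SYNEFF062	effector	RAB5;RAB15
SYNEFF063	effector	RAB5;RAB17
SYNEFF064	effector	RAB5;RAB19
SYNEFF065	effector	RAB5;RAB19
SYNEFF066	effector	RAB5;RAB19
SYNEFF067	effector	RAB5;RAB20
SYNEFF068	effector	RAB5;RAB22
SYNEFF069	effector	RAB5;RAB22
SYNEFF070	effector	RAB5;RAB22
SYNEFF071	effector	RAB5;RAB22
SYNEFF072	effector	RAB5;RAB22
SYNEFF073	effector	RAB5;RAB24
SYNEFF074	effector	RAB5;RAB24
SYNEFF075	effector	RAB5;RAB25
SYNEFF076	effector	RAB5;RAB25
SYNEFF077	effector	RAB5;RAB25
SYNEFF078	effector	RAB5;RAB25
SYNEFF079	effector	RAB6;RAB25
SYNEFF080	effector	RAB6;RAB26
SYNEFF081	effector	RAB6;RAB30
SYNEFF082	effector	RAB6;RAB30
SYNEFF083	effector	RAB6;RAB30
SYNEFF084	effector	RAB6;RAB31
SYNEFF085	effector	RAB6;RAB31
SYNEFF086	effector	RAB6;RAB31
SYNEFF087	effector	RAB6;RAB32
SYNEFF088	effector	RAB6;RAB32
SYNEFF089	effector	RAB6;RAB33
SYNEFF090	effector	RAB6;RAB33
SYNEFF091	effector	RAB6;RAB33
SYNEFF092	effector	RAB6;RAB33
SYNEFF093	effector	RAB6;RAB33
SYNEFF094	effector	RAB6;RAB33
SYNEFF095	effector	RAB6;RAB33
SYNEFF096	effector	RAB6;RAB33
SYNEFF097	effector	RAB6;RAB34
SYNEFF098	effector	RAB6;RAB34
SYNEFF099	effector	RAB6;RAB35
SYNEFF100	effector	RAB6;RAB35
SYNEFF101	effector	RAB7;RAB35
SYNEFF102	effector	RAB7;RAB35
SYNEFF103	effector	RAB7;RAB35
SYNEFF104	effector	RAB7;RAB36
SYNEFF105	effector	RAB7;RAB36
SYNEFF106	effector	RAB7;RAB36
SYNEFF107	effector	RAB7;RAB36
SYNEFF108	effector	RAB7;RAB36
SYNEFF109	effector	RAB7;RAB36
SYNEFF110	effector	RAB7;RAB37
SYNEFF111	effector	RAB7;RAB37
SYNEFF112	effector	RAB7;RAB38
SYNEFF113	effector	RAB7;RAB39
SYNEFF114	effector	RAB7;RAB39
SYNEFF115	effector	RAB8;RAB40
SYNEFF116	effector	RAB8;RAB40
SYNEFF117	effector	RAB8;RAB41
SYNEFF118	effector	RAB8;RAB41
SYNEFF119	effector	RAB8;RAB41
SYNEFF120	effector	RAB8
SYNEFF121	effector	RAB8
SYNEFF122	effector	RAB8
SYNEFF123	effector	RAB8
SYNEFF124	effector	RAB8
SYNEFF125	effector	RAB8
SYNEFF126	effector	RAB8
SYNEFF127	effector	RAB8
SYNEFF128	effector	RAB8
SYNEFF129	effector	RAB8
SYNEFF130	effector	RAB8
SYNEFF131	effector	RAB8
SYNEFF132	effector	RAB8
SYNEFF133	effector	RAB8
SYNEFF134	effector	RAB8
SYNEFF135	effector	RAB9
SYNEFF136	effector	RAB9
GDI1	general_machinery	
GDI2	general_machinery	
CHM	general_machinery	
CHML	general_machinery	
RABGGTA	general_machinery	
RABGGTB	general_machinery	
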