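parcel_id	parcel_name	hemisphere	network
1	VN_parcel001	L	VN
2	VN_parcel002	R	VN
3	SMN_parcel003	L	SMN
4	SMN_parcel004	R	SMN
5	DAN_parcel005	L	DAN
6	DAN_parcel006	R	DAN
7	VAN_parcel007	L	VAN
8	VAN_parcel008	R	VAN
9	LN_parcel009	L	LN
10	LN_parcel010	R	LN
11	FPN_parcel011	L	FPN
12	FPN_parcel012	R	FPN
13	DMN_parcel013	L	DMN
14	DMN_parcel014	R	DMN
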