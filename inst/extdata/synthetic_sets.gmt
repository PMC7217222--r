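SYNSET1	synthetic gene set	SYNG104	SYNG084	SYNG019	SYNG079	SYNG077	SYNG061	SYNG085	SYNG045	SYNG020	SYNG071	SYNG095	SYNG017	SYNG003	SYNG002	SYNG103	SYNG014	SYNG068	SYNG018	SYNG056	SYNG025	SYNG028	SYNG004
SYNSET2	synthetic gene set	SYNG028	SYNG038	SYNG065	SYNG031	SYNG098	SYNG076	SYNG042	SYNG034	SYNG070	SYNG054	SYNG017	SYNG008	SYNG095	SYNG046	SYNG059	SYNG085
SYNSET3	synthetic gene set	SYNG054	SYNG065	SYNG017	SYNG069	SYNG020	SYNG068	SYNG066	SYNG003	SYNG057	SYNG024	SYNG078	SYNG001	SYNG100	SYNG023	SYNG019	SYNG061	SYNG080	SYNG016	SYNG072	SYNG008	SYNG042	SYNG067	SYNG099	SYNG086
SYNSET4	synthetic gene set	SYNG101	SYNG100	SYNG014	SYNG072	SYNG008	SYNG032	SYNG025	SYNG036	SYNG006	SYNG013	SYNG065	SYNG058	SYNG104	SYNG004	SYNG009	SYNG057	SYNG042	SYNG079	SYNG094	SYNG078	SYNG066	SYNG026	SYNG097
SYNSET5	synthetic gene set	SYNG066	SYNG069	SYNG062	SYNG065	SYNG032	SYNG090	SYNG067	SYNG034	SYNG072	SYNG026	SYNG058	SYNG018	SYNG054	SYNG016	SYNG051	SYNG057	SYNG041	SYNG010	SYNG086	SYNG031	SYNG055	SYNG087
SYNSET6	synthetic gene set	SYNG086	SYNG039	SYNG101	SYNG016	SYNG100	SYNG020	SYNG092	SYNG083	SYNG085	SYNG047	SYNG019	SYNG033	SYNG018	SYNG060
SYNSET7	synthetic gene set	SYNG096	SYNG013	SYNG051	SYNG063	SYNG021	SYNG086	SYNG029	SYNG091	SYNG056	SYNG066	SYNG052	SYNG044	SYNG054	SYNG026	SYNG046
SYNSET8	synthetic gene set	SYNG012	SYNG093	SYNG047	SYNG003	SYNG044	SYNG071	SYNG059	SYNG057	SYNG091	SYNG050	SYNG043	SYNG067	SYNG080	SYNG038	SYNG066	SYNG009	SYNG015	SYNG101
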