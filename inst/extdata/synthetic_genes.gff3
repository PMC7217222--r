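##gff-version 3
# synthetic annotation generated for demonstration; gene ids and
# positions are invented and matched to the simulated genome
1	synthetic	gene	839563	864335	.	-	.	ID=SYNG001;Name=SYNG001
1	synthetic	gene	3022117	3033445	.	+	.	ID=SYNG002;Name=SYNG002
1	synthetic	gene	5084030	5101367	.	-	.	ID=SYNG003;Name=SYNG003
1	synthetic	gene	7195127	7207729	.	+	.	ID=SYNG004;Name=SYNG004
1	synthetic	gene	8734444	8750709	.	-	.	ID=SYNG005;Name=SYNG005
1	synthetic	gene	10672929	10687085	.	+	.	ID=SYNG006;Name=SYNG006
1	synthetic	gene	12268048	12345274	.	-	.	ID=SYNG007;Name=SYNG007
1	synthetic	gene	13830029	13943406	.	+	.	ID=SYNG008;Name=SYNG008
1	synthetic	gene	15564112	15651769	.	+	.	ID=SYNG009;Name=SYNG009
1	synthetic	gene	17669248	17750996	.	-	.	ID=SYNG010;Name=SYNG010
1	synthetic	gene	19221246	19255223	.	+	.	ID=SYNG011;Name=SYNG011
1	synthetic	gene	21304951	21422472	.	+	.	ID=SYNG012;Name=SYNG012
1	synthetic	gene	23108628	23168565	.	+	.	ID=SYNG013;Name=SYNG013
1	synthetic	gene	25175578	25196017	.	-	.	ID=SYNG014;Name=SYNG014
1	synthetic	gene	27263050	27375021	.	+	.	ID=SYNG015;Name=SYNG015
1	synthetic	gene	28871111	28952342	.	+	.	ID=SYNG016;Name=SYNG016
1	synthetic	gene	30761598	30779368	.	+	.	ID=SYNG017;Name=SYNG017
1	synthetic	gene	32853381	32866193	.	+	.	ID=SYNG018;Name=SYNG018
1	synthetic	gene	34873909	34968090	.	-	.	ID=SYNG019;Name=SYNG019
1	synthetic	gene	36703316	36769343	.	-	.	ID=SYNG020;Name=SYNG020
1	synthetic	gene	38582462	38626753	.	+	.	ID=SYNG021;Name=SYNG021
1	synthetic	gene	40270961	40367579	.	+	.	ID=SYNG022;Name=SYNG022
1	synthetic	gene	41856792	41937082	.	-	.	ID=SYNG023;Name=SYNG023
1	synthetic	gene	43907500	43977395	.	-	.	ID=SYNG024;Name=SYNG024
1	synthetic	gene	46172378	46236207	.	-	.	ID=SYNG025;Name=SYNG025
1	synthetic	gene	48310917	48325511	.	+	.	ID=SYNG026;Name=SYNG026
1	synthetic	gene	50347717	50407521	.	+	.	ID=SYNG027;Name=SYNG027
1	synthetic	gene	52641636	52691469	.	+	.	ID=SYNG028;Name=SYNG028
1	synthetic	gene	54654350	54714622	.	+	.	ID=SYNG029;Name=SYNG029
1	synthetic	gene	56855025	56870198	.	-	.	ID=SYNG030;Name=SYNG030
1	synthetic	gene	58711669	58807802	.	-	.	ID=SYNG031;Name=SYNG031
1	synthetic	gene	60834910	60905010	.	-	.	ID=SYNG032;Name=SYNG032
1	synthetic	gene	62407013	62522109	.	+	.	ID=SYNG033;Name=SYNG033
1	synthetic	gene	64190064	64257205	.	+	.	ID=SYNG034;Name=SYNG034
1	synthetic	gene	65753680	65854514	.	-	.	ID=SYNG035;Name=SYNG035
1	synthetic	gene	67932243	68012995	.	-	.	ID=SYNG036;Name=SYNG036
1	synthetic	gene	69730663	69829592	.	-	.	ID=SYNG037;Name=SYNG037
1	synthetic	gene	71931796	71982278	.	+	.	ID=SYNG038;Name=SYNG038
1	synthetic	gene	73915918	73967509	.	+	.	ID=SYNG039;Name=SYNG039
1	synthetic	gene	76056513	76076860	.	-	.	ID=SYNG040;Name=SYNG040
1	synthetic	gene	77618331	77651931	.	-	.	ID=SYNG041;Name=SYNG041
1	synthetic	gene	79253954	79355732	.	+	.	ID=SYNG042;Name=SYNG042
1	synthetic	gene	81171179	81227421	.	-	.	ID=SYNG043;Name=SYNG043
1	synthetic	gene	82755674	82782479	.	-	.	ID=SYNG044;Name=SYNG044
1	synthetic	gene	84676828	84753844	.	-	.	ID=SYNG045;Name=SYNG045
1	synthetic	gene	86320405	86432789	.	-	.	ID=SYNG046;Name=SYNG046
1	synthetic	gene	88397352	88438845	.	-	.	ID=SYNG047;Name=SYNG047
1	synthetic	gene	90273550	90368035	.	-	.	ID=SYNG048;Name=SYNG048
1	synthetic	gene	92015510	92040291	.	+	.	ID=SYNG049;Name=SYNG049
1	synthetic	gene	93700287	93725117	.	+	.	ID=SYNG050;Name=SYNG050
1	synthetic	gene	95890791	95926374	.	+	.	ID=SYNG051;Name=SYNG051
1	synthetic	gene	97899311	98013244	.	+	.	ID=SYNG052;Name=SYNG052
2	synthetic	gene	775509	817462	.	+	.	ID=SYNG053;Name=SYNG053
2	synthetic	gene	2428261	2488173	.	-	.	ID=SYNG054;Name=SYNG054
2	synthetic	gene	4567695	4646926	.	-	.	ID=SYNG055;Name=SYNG055
2	synthetic	gene	6199282	6294786	.	+	.	ID=SYNG056;Name=SYNG056
2	synthetic	gene	8178107	8297268	.	-	.	ID=SYNG057;Name=SYNG057
2	synthetic	gene	10095513	10152807	.	-	.	ID=SYNG058;Name=SYNG058
2	synthetic	gene	11704079	11772193	.	-	.	ID=SYNG059;Name=SYNG059
2	synthetic	gene	13269350	13299333	.	+	.	ID=SYNG060;Name=SYNG060
2	synthetic	gene	14988254	15051007	.	+	.	ID=SYNG061;Name=SYNG061
2	synthetic	gene	16603522	16653093	.	+	.	ID=SYNG062;Name=SYNG062
2	synthetic	gene	18210874	18215904	.	+	.	ID=SYNG063;Name=SYNG063
2	synthetic	gene	20273559	20291858	.	-	.	ID=SYNG064;Name=SYNG064
2	synthetic	gene	22417109	22425451	.	+	.	ID=SYNG065;Name=SYNG065
2	synthetic	gene	24135163	24220650	.	-	.	ID=SYNG066;Name=SYNG066
2	synthetic	gene	25790929	25879082	.	-	.	ID=SYNG067;Name=SYNG067
2	synthetic	gene	27655193	27739134	.	-	.	ID=SYNG068;Name=SYNG068
2	synthetic	gene	29652376	29673477	.	+	.	ID=SYNG069;Name=SYNG069
2	synthetic	gene	31664152	31730230	.	-	.	ID=SYNG070;Name=SYNG070
2	synthetic	gene	33671489	33717364	.	+	.	ID=SYNG071;Name=SYNG071
2	synthetic	gene	35322607	35341000	.	-	.	ID=SYNG072;Name=SYNG072
2	synthetic	gene	37598921	37638623	.	-	.	ID=SYNG073;Name=SYNG073
2	synthetic	gene	39824595	39850755	.	+	.	ID=SYNG074;Name=SYNG074
2	synthetic	gene	41539778	41614017	.	-	.	ID=SYNG075;Name=SYNG075
2	synthetic	gene	43193501	43288949	.	+	.	ID=SYNG076;Name=SYNG076
2	synthetic	gene	45488471	45562691	.	-	.	ID=SYNG077;Name=SYNG077
2	synthetic	gene	47662618	47780775	.	+	.	ID=SYNG078;Name=SYNG078
2	synthetic	gene	49892633	50008447	.	-	.	ID=SYNG079;Name=SYNG079
2	synthetic	gene	51936211	51989275	.	+	.	ID=SYNG080;Name=SYNG080
2	synthetic	gene	53809185	53915364	.	+	.	ID=SYNG081;Name=SYNG081
2	synthetic	gene	55867648	55943632	.	-	.	ID=SYNG082;Name=SYNG082
2	synthetic	gene	58035005	58069239	.	+	.	ID=SYNG083;Name=SYNG083
2	synthetic	gene	59786021	59898281	.	-	.	ID=SYNG084;Name=SYNG084
2	synthetic	gene	62061834	62172127	.	+	.	ID=SYNG085;Name=SYNG085
2	synthetic	gene	63771463	63844310	.	-	.	ID=SYNG086;Name=SYNG086
2	synthetic	gene	65644297	65745111	.	+	.	ID=SYNG087;Name=SYNG087
2	synthetic	gene	67173591	67282152	.	-	.	ID=SYNG088;Name=SYNG088
2	synthetic	gene	69168770	69207740	.	+	.	ID=SYNG089;Name=SYNG089
2	synthetic	gene	71394931	71479247	.	-	.	ID=SYNG090;Name=SYNG090
2	synthetic	gene	73363883	73474863	.	-	.	ID=SYNG091;Name=SYNG091
2	synthetic	gene	75246231	75261787	.	+	.	ID=SYNG092;Name=SYNG092
2	synthetic	gene	76853350	76888083	.	-	.	ID=SYNG093;Name=SYNG093
2	synthetic	gene	78559611	78608878	.	+	.	ID=SYNG094;Name=SYNG094
2	synthetic	gene	80565709	80652506	.	+	.	ID=SYNG095;Name=SYNG095
2	synthetic	gene	82568473	82659060	.	-	.	ID=SYNG096;Name=SYNG096
2	synthetic	gene	84742846	84758958	.	+	.	ID=SYNG097;Name=SYNG097
2	synthetic	gene	86650255	86757793	.	+	.	ID=SYNG098;Name=SYNG098
2	synthetic	gene	88651508	88679907	.	-	.	ID=SYNG099;Name=SYNG099
2	synthetic	gene	90818236	90866819	.	+	.	ID=SYNG100;Name=SYNG100
2	synthetic	gene	93075124	93132007	.	-	.	ID=SYNG101;Name=SYNG101
2	synthetic	gene	94996008	95098440	.	+	.	ID=SYNG102;Name=SYNG102
2	synthetic	gene	97256014	97281835	.	+	.	ID=SYNG103;Name=SYNG103
2	synthetic	gene	98889223	98897833	.	+	.	ID=SYNG104;Name=SYNG104
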