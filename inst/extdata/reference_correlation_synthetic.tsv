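gene	ARNTL	NPAS2	CLOCK	NFIL3	CRY1	CRY2	PER1	PER2	PER3	NR1D1	NR1D2	RORA	RORB	RORC	DBP	TEF	HLF
ARNTL	1	0.98855	0.96103	0.986607	0.500457	-0.380945	-0.959137	-0.599521	-0.917792	-0.274662	-0.708451	0.373998	0.868016	0.138901	-0.996638	-0.985752	-0.96302
NPAS2	0.98855	1	0.98397	0.99492100000000006	0.396887	-0.48707	-0.983022	-0.687805	-0.956873	-0.161694	-0.620399	0.263226	0.804351	0.022293	-0.988293	-0.994585	-0.984136
CLOCK	0.96103	0.98397	1	0.986345	0.255684	-0.611125	-0.994944	-0.789267	-0.987276	-0.011853	-0.497337	0.117684	0.708117	-0.127648	-0.961199	-0.987096	-0.995404
NFIL3	0.986607	0.99492100000000006	0.986345	1	0.385874	-0.495854	-0.985156	-0.696132	-0.959611	-0.148887	-0.612304	0.252537	0.79731	0.010592	-0.987206	-0.994708	-0.987599
CRY1	0.500457	0.396887	0.255684	0.385874	1	0.601426	-0.251135	0.384067	-0.129454	-0.964001	-0.961055	0.98482	0.857932	0.920392	-0.496135	-0.375973	-0.268173
CRY2	-0.380945	-0.48707	-0.611125	-0.495854	0.601426	1	0.613271	0.962216	0.706207	-0.775391	-0.374611	0.707789	0.117975	0.857249	0.385977	0.5056	0.600317
PER1	-0.959137	-0.983022	-0.994944	-0.985156	-0.251135	0.613271	1	0.790361	0.987346	0.007713	0.493986	-0.112703	-0.705328	0.131926	0.959654	0.986427	0.993756
PER2	-0.599521	-0.687805	-0.789267	-0.696132	0.384067	0.962216	0.790361	1	0.860529	-0.596299	-0.131478	0.509049	-0.133972	0.702815	0.602662	0.703587	0.780543
PER3	-0.917792	-0.956873	-0.987276	-0.959611	-0.129454	0.706207	0.987346	0.860529	1	-0.11528	0.381867	0.010827	-0.612673	0.253309	0.919904	0.963091	0.985282
NR1D1	-0.274662	-0.161694	-0.011853	-0.148887	-0.964001	-0.775391	0.007713	-0.596299	-0.11528	1	0.86618	-0.986455	-0.70744	-0.98442	0.27042	0.138089	0.025857
NR1D2	-0.708451	-0.620399	-0.497337	-0.612304	-0.961055	-0.374611	0.493986	-0.131478	0.381867	0.86618	1	-0.914693	-0.959235	-0.790828	0.704518	0.601745	0.508702
RORA	0.373998	0.263226	0.117684	0.252537	0.98482	0.707789	-0.112703	0.509049	0.010827	-0.986455	-0.914693	1	0.77864	0.964016	-0.369924	-0.24154	-0.130144
RORB	0.868016	0.804351	0.708117	0.79731	0.857932	0.117975	-0.705328	-0.133972	-0.612673	-0.70744	-0.959235	0.77864	1	0.603381	-0.865406	-0.790793	-0.716677
RORC	0.138901	0.022293	-0.127648	0.010592	0.920392	0.857249	0.131926	0.702815	0.253309	-0.98442	-0.790828	0.964016	0.603381	1	-0.133875	0.001052	0.114563
DBP	-0.996638	-0.988293	-0.961199	-0.987206	-0.496135	0.385977	0.959654	0.602662	0.919904	0.27042	0.704518	-0.369924	-0.865406	-0.133875	1	0.986493	0.963542
TEF	-0.985752	-0.994585	-0.987096	-0.994708	-0.375973	0.5056	0.986427	0.703587	0.963091	0.138089	0.601745	-0.24154	-0.790793	0.001052	0.986493	1	0.987089
HLF	-0.96302	-0.984136	-0.995404	-0.987599	-0.268173	0.600317	0.993756	0.780543	0.985282	0.025857	0.508702	-0.130144	-0.716677	0.114563	0.963542	0.987089	1
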