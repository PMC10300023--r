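context	SBS5_synth	SBS6_synth	SBS29_synth	SBS3_synth	SBS30_synth
A[C>A]A	0.002422	0.006537	0.018541	0.006798	0.000924
A[C>A]C	0.006972	0.027538	0.071402	0.004189	0.000958
A[C>A]G	0.007277	0.03426	0.052907	0.003434	0.001346
A[C>A]T	0.011115	0.002763	0.054841	0.003575	0.000576
C[C>A]A	0.005674	0.000216	0.033368	0.010885	0.002876
C[C>A]C	0.004428	0.003918	0.055705	0.002849	0.001017
C[C>A]G	0.005716	0.001241	0.081636	0.003064	0.001791
C[C>A]T	0.005985	0.000183	0.043892	0.017181	0.002836
G[C>A]A	0.007419	0.002216	0.055399	0.00561	0.000349
G[C>A]C	0.003702	0.002856	0.06436	0.003481	0.000793
G[C>A]G	0.008209	0.011447	0.055506	0.005335	2.1e-05
G[C>A]T	0.009698	0.0019	0.063633	0.006181	0.004762
T[C>A]A	0.007567	0.001971	0.068508	0.006871	0.000971
T[C>A]C	0.003613	0.000459	0.076897	0.003224	0.008447
T[C>A]G	0.011954	0.005442	0.0343	0.002292	0.004796
T[C>A]T	0.006204	0	0.058294	0.004623	0.004126
A[C>G]A	0.009986	0.002754	0.000594	0.003799	0.009044
A[C>G]C	0.009201	0.001628	6.5e-05	0.003851	0.011667
A[C>G]G	0.004248	0.005637	4.7e-05	0.002058	0.000411
A[C>G]T	0.009896	0.00077	8e-06	0.003426	0.000947
C[C>G]A	0.012018	0.001734	0.001022	0.011285	0.027695
C[C>G]C	0.009056	6.5e-05	0.000654	0.010024	0.0217
C[C>G]G	0.011741	0.004863	0.00257	0.000723	0.01127
C[C>G]T	0.007704	0.003268	0.000159	0.006679	0.011575
G[C>G]A	0.008227	0.000128	5e-05	0.007549	0.001278
G[C>G]C	0.005227	0.000801	7e-06	0.007237	0.00134
G[C>G]G	0.012041	0.003577	0.00276	0.014165	0.000208
G[C>G]T	0.003718	8e-06	0.00198	0.00386	7e-04
T[C>G]A	0.007463	0.009908	0.000396	0.004757	0.001481
T[C>G]C	0.003407	7.8e-05	7.1e-05	0.007761	0.004715
T[C>G]G	0.013309	0.000873	0.002738	0.018616	0.002683
T[C>G]T	0.007928	1.5e-05	3.6e-05	0.010871	1.3e-05
A[C>T]A	0.010661	0.00063	0	0.002828	0.131808
A[C>T]C	0.013266	5.6e-05	0.008561	0.010288	0.138564
A[C>T]G	0.021777	0.132834	1.1e-05	0.009623	0.18261
A[C>T]T	0.014136	0.002475	0.000122	0.003376	0.12701
C[C>T]A	0.019351	0.000238	4.4e-05	0.006078	0.013815
C[C>T]C	0.012207	0.013282	0.000662	0.001707	0.008612
C[C>T]G	0.007961	0.206183	0.001403	0.006347	0.018908
C[C>T]T	0.014374	0.000337	0.000118	0.005751	0.010356
G[C>T]A	0.013857	0.000858	0.002193	0.008121	0.000382
G[C>T]C	0.020886	3.7e-05	0.000945	0.003519	0.002067
G[C>T]G	0.022651	0.200191	0.001381	0.009828	0.000219
G[C>T]T	0.007755	0.004492	0.000877	0.007788	0.005487
T[C>T]A	0.021876	6.2e-05	0.003553	0.003599	0.011336
T[C>T]C	0.015494	0.000258	0.000449	0.005158	0.009366
T[C>T]G	0.028569	0.133775	3.4e-05	0.009805	0.014996
T[C>T]T	0.012419	0.000535	1.2e-05	0.003541	6.2e-05
A[T>A]A	0.012373	0.004495	0.003912	0.022364	0.000763
A[T>A]C	0.017534	0.000786	1e-06	0.0092	0.000262
A[T>A]G	0.006764	0.000514	0.000326	0.018849	0.013042
A[T>A]T	0.00695	0.000108	0.000461	0.024377	0.002242
C[T>A]A	0.005536	0.000111	0.000722	0.020079	0.001122
C[T>A]C	0.007965	0.000586	0.00012	0.013443	0.000171
C[T>A]G	0.006004	0.002193	0.00013	0.018546	0.000176
C[T>A]T	0.00878	0.001892	0.000306	0.04254	0.000224
G[T>A]A	0.010536	0.000251	0.002012	0.024916	0.004301
G[T>A]C	0.006025	0.000201	0.00015	0.003904	6e-06
G[T>A]G	0.009115	0.002565	0.000147	0.020675	0.000175
G[T>A]T	0.007876	0.000946	0.004082	0.025977	0.003539
T[T>A]A	0.007718	0.005637	0.000235	0.017706	0.003363
T[T>A]C	0.0033	0.008167	0.000411	0.015383	0.00146
T[T>A]G	0.005859	0.007712	0.004945	0.020689	0.011295
T[T>A]T	0.00808	1e-06	0.000281	0.027917	0.021269
A[T>C]A	0.015839	0.006187	0.000102	0.008682	0
A[T>C]C	0.017608	0	0.000613	0.005174	0.000621
A[T>C]G	0.019232	0.000936	0.000736	0.004161	0.006753
A[T>C]T	0.014027	0.000152	0.000289	0.006488	0.00031
C[T>C]A	0.009469	0.007578	0.001407	0.005359	0.008996
C[T>C]C	0.01544	0.002232	7.8e-05	0.005408	0.007071
C[T>C]G	0.012034	0.013318	6e-06	0.00534	9.3e-05
C[T>C]T	0.012846	0.000198	0.00572	0.003577	0.003229
G[T>C]A	0.018711	0.0141	0.00017	0.00685	0.002154
G[T>C]C	0.014425	0.006712	0.01282	0.005367	0.017363
G[T>C]G	0.019484	3e-06	0.004633	0.00637	0.000145
G[T>C]T	0.014837	0.000789	0.004696	0.006388	0.013041
T[T>C]A	0.009342	0.003328	0.002766	0.012761	5e-06
T[T>C]C	0.015676	0.000148	0.00059	0.002388	0.003476
T[T>C]G	0.015305	4e-06	0.00534	0.009959	0.002599
T[T>C]T	0.01216	0.001365	0.00083	0.00301	0.004342
A[T>G]A	0.009057	0.003167	0.000586	0.017292	0.000168
A[T>G]C	0.004107	0.002208	0	0.018497	0.000219
A[T>G]G	0.010485	0.002486	0.007013	0.04659	2e-06
A[T>G]T	0.009461	0.013833	0.003079	0.015445	0.002207
C[T>G]A	0.004478	0.009073	0.000302	0.011778	0.002754
C[T>G]C	0.007557	0.001688	0.000135	0.008313	0.006425
C[T>G]G	0.012079	0.000414	2e-05	0.015782	0.002354
C[T>G]T	0.005659	0.001102	0.001495	0.022686	0.000228
G[T>G]A	0.003207	0.001574	3.9e-05	0.013035	0.022443
G[T>G]C	0.004344	0.003635	7e-06	0.014887	2.7e-05
G[T>G]G	0.010396	3.1e-05	0.00067	0.012272	0.008196
G[T>G]T	0.013809	0.006922	0.001397	0.00911	0.000615
T[T>G]A	0.013252	0.000619	0.000544	0.017084	0.000232
T[T>G]C	0.009637	0.004029	0.000141	0.009793	0.000132
T[T>G]G	0.008061	0.000207	0.002787	0.006978	0.000429
T[T>G]T	0.007198	0.020499	4.3e-05	0.033003	0.001049
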