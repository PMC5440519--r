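# Family-diagnostic degenerate protein motifs for the K+ transporter screen.
# Pattern strings are kept verbatim, including the stray leading "(" of the
# KEA motif (stripped by the loader). The three channel pore motifs
# (CH-6..CH-8) serve both the voltage-gated and TPK/KCO screens.
pattern_id	family	pattern
HAK-1	HAK/KT/KUP	[A,G] [D,S,G]-[V,L,I,M]-x-x[S,A]-P-L-Y
HAK-2	HAK/KT/KUP	[A,G]-[N,D,H,S]-[D,N]-x-G-[E,Q,D,N]-[A,G]
HAK-3	HAK/KT/KUP	[A,G,S]-[D,N] [G,S,A,C]-x-[L,I,V,F]-x-P-x-[V,I,L,M]-[A,S]
HAK-4	HAK/KT/KUP	G-[S,A,T,C]-E-[A,G]-x-[F,Y]-A-[D,N,E]-[L,I,V]-[G,C,S,A]x-F
HAK-5	HAK/KT/KUP	[Y,F]-x-x-x-x-x-[H,F,Y]-G-Y-x-[E,D]
CH-6	VG-channel	[S,T]-x-xT-x-G-[Y,F,L]-G-[D,E]
CH-7	VG-channel	R-[L,F]-x-R-[L,V,I,A,G]-x-[R,C,K][V,A,L,M]
CH-8	VG-channel	[A,V,S]-Y-[L,I]-[I,L]-G-[N,I]-[M,I]-T-[N,A]-L[V,I]
HKT-9	HKT	[S,T,A]-x-[F,Y,V,L,C]-x-[D,N,S]G
HKT-10	HKT	[G,A]-[Y,F]-[G,A]-x-[V,A,I]-G-[L,M,Y,F]-[S,T]
KEA-11	KEA	(G-x-G-x-x-G-x(n)-[DE]
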