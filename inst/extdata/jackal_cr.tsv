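#L=440
haplotype_id	site:15465	site:15466	site:15485	site:15494	site:15498	site:15510	site:15518	site:15527	site:15528	site:15529	site:15530	site:15531	site:15536	site:15586	site:15611	site:15613	site:15619	site:15621	site:15629	site:15633	site:15634	site:15636	site:15639	site:15654	site:15711	site:15750	site:15751	count:GJ	count:UP	count:RJ	count:UA	count:HR	count:KR	count:MP	count:Central India	count:Israel	count:Bulgaria	count:Serbia	count:Croatia	count:Italy	count:Austria
Ind1	C	-	A	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	A	C	A	C	2	3	3	0	0	0	0	0	0	0	0	0	0	0
Ind2	C	C	A	G	C	T	-	T	-	-	C	C	T	A	G	T	A	T	C	T	T	A	C	G	C	A	C	4	0	0	0	0	0	0	0	0	0	0	0	0	0
Ind3	C	C	A	G	C	T	-	T	T	T	C	C	C	A	G	T	A	T	C	T	T	A	C	G	C	A	C	4	0	0	0	0	0	0	0	0	0	0	0	0	0
Ind4	C	-	A	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	G	C	A	T	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Ind5	C	-	A	G	T	C	-	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	G	T	A	C	16	0	0	0	0	0	0	0	0	0	0	0	0	0
Ind6	C	-	A	A	T	T	A	C	-	-	C	T	T	G	G	T	A	T	C	T	T	A	C	A	T	A	C	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Ind7	C	-	A	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	A	T	A	C	0	0	0	0	2	0	0	0	0	0	0	0	0	0
Ind8	C	C	A	G	T	T	-	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	G	T	A	C	2	0	0	1	0	0	0	0	0	0	0	0	0	0
Ind9	C	-	A	G	T	T	A	C	-	-	C	T	T	A	G	C	A	T	C	T	C	A	C	G	C	A	C	0	0	0	0	0	3	0	0	0	0	0	0	0	0
Ind10	C	-	A	G	T	T	A	C	-	-	C	T	T	G	A	T	A	T	C	T	T	A	C	G	C	A	C	0	0	0	0	0	0	2	0	0	0	0	0	0	0
Ind11	C	-	A	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	C	G	C	A	C	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Ind12	C	-	A	G	T	T	-	C	-	-	T	C	T	A	G	T	A	T	T	T	T	A	C	A	C	A	C	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Ind13	C	-	A	G	T	T	A	C	C	-	C	T	T	A	G	T	G	T	C	T	T	A	C	G	C	A	T	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Ind14	C	-	G	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	T	T	A	T	A	T	A	C	0	0	0	0	0	0	1	0	0	0	0	0	0	0
Ind15	C	-	A	G	T	T	A	C	-	-	C	T	T	G	G	T	A	T	C	T	T	A	C	G	T	A	C	0	1	0	1	0	0	0	0	0	0	0	0	0	0
Ind16	-	-	A	G	T	T	A	C	-	-	C	T	T	A	G	T	A	T	C	C	T	G	C	A	C	A	C	0	0	0	0	0	0	0	2	0	0	0	0	0	0
Isr	C	-	A	G	T	T	A	C	-	-	C	T	T	G	G	T	A	C	C	T	T	A	C	A	T	A	C	0	0	0	0	0	0	0	0	2	0	0	0	0	0
Eur	C	-	A	G	T	T	A	C	-	-	C	T	T	G	G	T	A	T	C	T	T	A	C	G	T	G	C	0	0	0	0	0	0	0	0	0	60	129	50	7	1
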