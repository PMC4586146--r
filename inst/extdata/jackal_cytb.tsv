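#L=412
haplotype_id	site:14279	site:14289	site:14319	site:14334	site:14352	site:14360	site:14393	site:14571	site:14669	count:UP	count:UA	count:HR	count:RJ	count:GJ	count:MP	count:KR	count:Central India	count:Israel	count:Bulgaria
cytb_Ind01	T	T	C	T	T	G	T	A	G	6	1	2	2	0	0	0	0	0	0
cytb_Ind02	T	T	C	T	T	G	T	G	G	2	0	0	0	3	2	0	0	0	0
cytb_Ind03	T	T	C	T	C	G	T	G	G	0	0	0	0	6	0	0	0	0	0
cytb_Ind04	T	T	C	T	T	G	T	G	A	0	0	0	0	0	0	2	0	0	0
cytb_Ind05	T	T	C	T	T	G	C	G	G	0	0	0	0	3	0	0	0	0	0
cytb_Ind06	T	C	C	T	T	G	T	G	G	0	2	0	0	0	0	0	0	0	0
cytb_Ind07	T	T	T	T	T	A	T	G	G	0	0	0	0	0	0	0	2	0	0
cytb_Isr	T	T	C	C	T	G	T	G	G	0	0	0	0	0	0	0	0	2	0
cytb_Blg	A	T	C	C	T	G	T	G	G	0	0	0	0	0	0	0	0	0	5
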