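accession	label	read_pairs	bases
SRR12763132	female_head	19605733	4901433250
SRR12763131	female_body	28525717	7131429250
SRR12763130	male_head	20632837	5158209250
SRR12763129	male_body	51464662	12866165500
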