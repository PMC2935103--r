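lineage	position	ref	alt	kind
l1	4	G	A	substitution
l2	4	G	A	substitution
l3	4	G	A	substitution
l1	6	A	G	substitution
l2	5	C	T	substitution
l3	5	C	A	substitution
l2	12	G	T	substitution
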