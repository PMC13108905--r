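gene_id	class	p
1	negative	-0.4
2	wild_type	-0.03
3	control	
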