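{"gene":"TOY4","strand":"+","seqname":"toy4_locus","exons":[{"id":1,"start":20,"end":80},{"id":2,"start":120,"end":170},{"id":3,"start":215,"end":270},{"id":4,"start":320,"end":390}],"alt_first_exon_starts":0,"annotated_starts":[]}
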