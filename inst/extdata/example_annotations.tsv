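gene_id	set_label	annotated	go_terms
aut_g00001	autosomal	FALSE	
aut_g00002	autosomal	FALSE	
aut_g00003	autosomal	TRUE	GO:0005737;GO:0016020;GO:0005575
aut_g00004	autosomal	TRUE	
aut_g00005	autosomal	TRUE	GO:0005739;GO:0009507;GO:0005575
aut_g00006	autosomal	TRUE	
aut_g00007	autosomal	TRUE	GO:0009507
aut_g00008	autosomal	TRUE	GO:0005829;GO:0003674;GO:0005575
aut_g00009	autosomal	TRUE	GO:0005737;GO:0005829;GO:0005886
aut_g00010	autosomal	TRUE	GO:0005739
aut_g00011	autosomal	TRUE	GO:0005739;GO:0009507;GO:0005829;GO:0005737
aut_g00012	autosomal	TRUE	GO:0005634;GO:0009536
aut_g00013	autosomal	FALSE	
aut_g00014	autosomal	TRUE	GO:0009507
aut_g00015	autosomal	TRUE	GO:0005739;GO:0009507;GO:0005634;GO:0005886;GO:0005740
aut_g00016	autosomal	FALSE	
aut_g00017	autosomal	FALSE	
aut_g00018	autosomal	TRUE	GO:0009507
aut_g00019	autosomal	TRUE	GO:0009507;GO:0005575;GO:0005773;GO:0005737
aut_g00020	autosomal	TRUE	GO:0016020;GO:0008150;GO:0042651
xl_g00001	X-linked	TRUE	GO:0005575
xl_g00002	X-linked	TRUE	
xl_g00003	X-linked	FALSE	
xl_g00004	X-linked	FALSE	
xl_g00005	X-linked	TRUE	GO:0005739;GO:0009507;GO:0016020;GO:0042651;GO:0005773
xl_g00006	X-linked	TRUE	GO:0009507
xl_g00007	X-linked	FALSE	
xl_g00008	X-linked	TRUE	GO:0016020;GO:0005634;GO:0005575
xl_g00009	X-linked	TRUE	GO:0005739;GO:0005740
xl_g00010	X-linked	FALSE	
xl_g00011	X-linked	TRUE	GO:0005739
xl_g00012	X-linked	TRUE	GO:0005886
xh_g00001	X-hemizygous	TRUE	GO:0003674
xh_g00002	X-hemizygous	TRUE	GO:0005773
xh_g00003	X-hemizygous	TRUE	GO:0005773;GO:0005634
xh_g00004	X-hemizygous	TRUE	GO:0009507;GO:0005634;GO:0042651
xh_g00005	X-hemizygous	TRUE	
xh_g00006	X-hemizygous	TRUE	GO:0005739;GO:0005773;GO:0003674
xh_g00007	X-hemizygous	TRUE	GO:0009507;GO:0009536;GO:0003674;GO:0005773
xh_g00008	X-hemizygous	TRUE	GO:0005739;GO:0009507;GO:0005634
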