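>PDGFRA_3UTR_segment sense-strand 99-nt oligonucleotide spanning the two miR-34a sites
TCGATATGTATATATGTATTTCTATATAGACTTGGAGAATACTGCCAAAACATTTATGACAAGCTGTATCACTGCCTTCGTTTATATTTTTTTAACTGT
>PDGFRA_3UTR_segment_antisense complementary oligonucleotide of the same segment
GGCCACAGTTAAAAAAATATAAACGAAGGCAGTGATACAGCTTGTCATAAATGTTTTGGCAGTATTCTCCAAGTCTATATAGAAATACATATATACATA
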