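>t1
GGCGCATAACCTATACGGTTTGACATTTGTGTCCGGGAGTGGAATAAAGAGCCATCCAAT
CACATACCTCTGCGGACGAATCGGCTTAGGCTTAGTATGAGGTAGAAAGACGGTACGGCT
TATGTAGGGTTGTATGAGCAGAGGGTAGGACGATAGTTTTGCTAGGGAAGTGAGTCTACT
GGGGCTAGGTGTGTGGCTACATTCTTGTCCAGGGAAGTATTCTTATGATCAAGAAATGTA
TTGCGTTATATGTAAAAGACTGCGAAGTTCGTAAAACGATCTAGAATTGGCAAACAGCGC
>t2
AGTGTGTAACCTATACGCGTCGACATATGTGTACAGAGGTGGAAGAAAGAACGATCCTGT
AACATACCCCCGCGCACACAAGATATTAGGAACAGTATCAGATGAAAAGCGGGTAAGACG
AATGTAGAGTAGTGTGCGTTGAAGGTAGGAAGATAGTGTTGCTAAGTAGGCGAGTCGACT
TGGGCCGGGTGTGTAGCTACAATATTGTCCAATGCAGTATTTTTCTGAGGAACAACTGAA
TGGCGATATATATAAGACACTGCGAAGTTAGCAAAGCAGTCTAACATGTGCAGAGAGCGC
>t3
GGTACATATTCTATACGGTTCAACATTTGTGTCGCCAGGTGGAATATATAGCAATCCAGT
AACTTGCCTCCGCGTATAGATCGGATTATGTTTAATGTGAGGTGAAATGTCGACAAAACG
AGTGAAGGCTGGGACGCACAAAAGGAAGGACCAGAGTTTGGGTATGTGAGTTAGCCTATT
TGTGCATAGGGTGTAGCCGCGTTAGAGTCTAGGGCAGTGTTTTTGTGAGGAAGACATAGA
GTGCGAGATTCATCAGACGAATACAAGTTAGTAAGACGGTCTGACATTGGCAGGGGGCGA
>t4
AGTGATTAACGCATACGTTTCAACATTTATGTCCACGAGTGAAATATAGGGCAGTCCAGT
GACATTACTCTGCGAGTAAATTGGCTTCAGTTTAATATAAAGAGGGAGGTCGACAAAATG
AGTTGACTGCAGAGCGCACATACTGCAGGACAATAGTTTCTCTAGGGTAGTTAGCCTACT
GGGGCCTGGGTGGTAGACTCGTTATAGCATAGGGCAGTATTCACATAAGGGAGACAGATA
TTACAGTATCCATAGTAGAATTGTTGGTTAGTAAATCGGTCTTCGGCCGGCGGGGCGAGA
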