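>IGHV1-1
GGCACAGCTTGGGAGACTTTACCAGCACTATCCATTTCGGCTTATGGTATCCCAACACTGGCGGACGGGCAGATTAAGCCCAAACGTGCCGTCTTTATTTCTTGATGACATTGGCACCGTTGGTGGAATCGTCCCGCTCTGAATGATCCACGGATCAAGATCGATGACAAGCTCAACTCAGGGCCCTCGTGTTACCCTCCCTCTGCAGTCCTCTAGTCTCCAAAGCAGCAAATGGCGCTGCGGCACTCTAGGAGGGCGAACCTGTACTCAAAAGGAAAAG
>IGHV1-2
TGCTGATATTGTACAATGGGCACATAGTGCGCAGCAAATCTGTAAGAATGGTCAAGCATCGACCCCTTCGAGTCTCTCACCTACCTGCCAAGTAACCCTCATAATGGCTGAAACGGCAAGCTAGATTACCGCCTCATATCTCGTCCTATTGGGATCGGTCATCTTAGTCACCTCCCGCGCCAAATCGACTCTATTAGTCAACTCCTTTTCAACTGACATGTCGGGTGGACTCGGGTATTTGGTGACTCCCTCTACAGTCAGGGTGCAGGTGCAAGGATAT
>IGHV2-1
AGAACCTCCTCAGTTCAGACCGCATCTGCTGACTTCGGGCGATTCGTACGTCTCGCTTATTGCCCAACGCGCTTTGCCTAATGGAGTACTCATTCGCGTCGTTAGTTAGCAAGTATCTGTCCGATGGTAGTAGAGAGTAGCTGACCGGGATCACATTTCCTACCAGCAGGGCACGGGAGATATCATTGAATGAGCAATATACGTCTCCGATGTTTGTCGGAGCGGCCAATTACAACCGCGGAGTGGTAAGCTTTTATTATGAAGTAACCTAAACTATGGG
>IGHV3-1
AGGACCAGTCCTTCATCTGGCAAGGAGGCAGCGCGGGAGCAGCGAAATACGCGGGAAACGTCCGTCTGCATCCTAGCGACATTAGAACTGGATTCTTTGCTAGGCTTGAATGAAGTCGATAGATCTCCAATTTCGATAGACATACCCCCGGTGGGTTCGGAACAATTTGACTGCACTTTTTCTCGTAAGTTGAAAAGGCTCTTAGCGCATGCGGGTTGATTCGCGGCCTACAAAAAAGGTGTGCGGGACCAAAACCAATGGAGCGAAACCACTTGATACC
>IGHV3-2
AAGCCATGCAGGTGGGCAACCTTGACCTCTCAACCACAACAGTTTAATGTGGCGGGGGCCGACTGGCGGTATATTAACGCCATGTATGGAGTTGCTGAACCACCCCGCGTAGAGCGTACCTCCGGTTGGTTCTCGTTCTTATTTAGAAATGTGCTTCTGGATGCCCTTCGAGAAATACGTAACCTAATCATACATCAAATTATCGATAACGCCAGACCTGTAGTGCACTATCTGACTACATGAGGTTGCAGGTAGATTATTGGCATTAATAATACCCCGC
>IGHV3-3
TATTCTCCGCTTAAGGACAGCTACCGGCATAATCCTTTAGGCGTTCCTCAAGTAGCGCATTTCACGATGCCCAGGTTTCGCACGAGCGTACTACTATAAGAATGAATCCACGACTAGTTGTCCTCCTCAGTTAGTGAGGAACCTAGAGAGACCTTATAGGCACTGGAATGCCCCTTTTGGCTCTCCGCCGAGGAGGGAACTTGGTTCTCTTCAGATGCTCACCTACAGGTCGTGGTCAGCACGTTCGCTTGATGCGCGTATGCTCCGACGACGGGCTAAG
>IGHV4-1
CTGTCTCTCAATGTGCCGGGAGATATATTGACTCACGGAAGTCCACCCGGCATTGCACTAATAGGAACGCTCGCCAGATTGTTGATAACTGTCCGTGAGGCCGGTCTACAACCGCGGACTCGACTGATCAGAGTGACCTTCATTAATTAGCAGAACGCATTTGTCTTATGACTGGCTACATATGCCCGGTCGCTACCTGGGTGTCGCGAGGATACTCGCACCAGACAGCTTTCTGGACATGGCCAAAAGAGCTAGCCAAGAAGGAAGGTTTCTCGTTCAC
>IGHV4-2
AGTGAGCATGCTTATTGGCACAGTCGGGTGGCGTCTTCTCAGTTGCGGCCGCGCACGCTGATTTGTCCAGCAAGGTCTACGCGCTATAGAACTGACGTGTACAAGGAGGCAACAAAAACGGAGGCGTATATGCCAATCCCGTAGGCCGGGACAGGGACAGCTCGTTTGCGGACTATTTGCATGATCCCTGAGGTTGAAATAAGGTAATTTCGACCAGTTGTGTCGCGCTATAGCTTCGCGGCGGTCTTGCTCTTATGTGGCGTGTGCCTTTTCGTTTGTT
>IGHV5-1
TCAGCTTTTTCGCCCAATGGTCGGCGCACCTTAGTCGATACCGGCATATGGCGTGAAATTTTATGAGAGCCTTTTTACCTCCTAATCGGCACTTCAGTGATACAACGTAAGATCATATGTGAAGAGACTAAGGGAGCCATTTATGTTCGCTAGGCAATGCGAGAGTGCGTGTTGCGCCTAGCTCGGAACGCTTCTTATCCTCATTCCCCCGTGATTGGGTATTACTCGCTCATCCCTAACGAAGGTTCAAGACAACTGGTCCGGATGGACTGAAGGGGTT
>IGHV6-1
TTGGCGGATAACACTGCAATTTTCCCTATGACAGTGGTTTCACTTGAGCACTCTTAAAGTACGCCATATCTACTGGGCTACTCATTCGGTCGACTTGTTACGTAATGGTAGAGAACAGGCTGAACATTCATACTGCTTTACCTCCTCTTTTCGCACGATACTCAGGTTTCAGCTAGTATGAGTTTCGACTGTCCTACCCGGTGTAAAGCTACCATAGTCATCCATTCTCCGTGTCGGGGCACACCAGCTCAGCCGATGTACGTGCCTATAGATGGAGGCA
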