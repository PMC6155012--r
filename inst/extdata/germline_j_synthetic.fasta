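>IGHJ3
AGTAGTATGCATACACCCCTCCGACTCCACTGAAGGTCGTCGAGC
>IGHJ4
TGGGCCTTCTACTCTTGCTCGTGCTAATTCCCTTTATCAACATCC
>IGHJ5
GAACACGACACCGCGGTCAGTTGCGATCTTGTAACATAGGACTAG
>IGHJ6
GAAGTTCGGCAAGGGCCCACTCGTTCGCATATCCATGAGTATTAC
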