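>SYNTH_J01859_FRAME synthetic 1542-nt stand-in for the E. coli J01859.1 16S rRNA coordinate frame (not the real sequence)
CACATTGATGTAACGCGCGCATCGCTGGTTAGTCAATAACGCAGAATCTAACGAATAGTATTCCTTCGGCTCTGGGGGTA
GAATTCCAACAAAGAGCGATGACGCCCGCGCGGAGCATTTTTTTCTGCCGTTGACAGGCCCGGTAGTTGACCTCATGGCC
CCCCCAGGTACAGGCCTTAAGCGGCCCCACCGAGTATTTCTGAAATCGGTTCCTGTCAACCCTCGTTACGGCACTCGTCA
CCTTGTGTCTAGAGGGGCCAGTACATTCACGATGCTAAAAACTGACGGGTGGGACAACGACATTAGCAATGGCGGCAAAA
GCGCACAGGACAGGGAGGTTCCCCGGGCGTAGTACGGTTATCAGGGCTGAGATAGAAGCCGTCCGGGTGTAGTTTGGTAA
GTCGACTCGCAACACTGCCCAAGCATTAAATACGATCTCTACATCCTTAATTATGGCCTAGACCGTCCCCTGACTGGGAT
CCCGAAAGTCACCCAAGCACTCAGGTGCAGTCGGGTCATTCACGGGCGCACGGGAGTCCAATGATTGTTTTACACGTTAG
TAGTTTATAGATTACAGAGCAAGCATAAACGAGTGATTTGCACATAAGGAACCGAGACACGCCCAAGCCACTAGAGTTCA
AGGGGGACATCAGTCTCTCAAGCCACATCACAGGGAGACCTTCGGCGAACACAAGGCGCCGAATCTACACGGAAAGATGC
TACAAACGGGTATACCAACAGGACGGCTGGAAGGGACACACTACCTTTGCCTGTATATGGTTCGTCTGTCCCTATCACGG
TGGTGGCAAACAAGGGGGACTCGCTGACCAGAGCGCCGAAGGGGTCCGAGGAATGGGCTGATCGAGAGCACTATCGGATT
GCCGCAGCGGCATTCTTGCCGAAGTAAGAGCTGAGCCGTGCACAGAATTCTTTAGACACGGCAAGCGCGTTAAGGATGTA
TGATGAAGTTGTCGAGGCAGCACTTATGGGCTTACCCACGTAAAGGTCTTAAGTGCGGTCTAGTAGAATAGTTCACGGGC
CTAGTGGTGTTTAATGCATGGGAGGATTTGACAAAGTCCGGCCGTAAATAAGATGAATACAAGCATGAGGCATTACGTAT
ACTACAAGGCGTCGGTTCAACGCACTCACCCCCGTAACGTTGTCCTCGTCAAGTCAATACGTTGAGATCCTAGTGCGGCG
GTTCCCACGGCCGGCGGGTGGCGCGCCATAGTGTGATGACCTTGTGGCTGCGGGGCGGTCGTTTGTTTATTAGGTTTCGA
GTCGCGCGTTGAATGCGAGGGTCTCATAAATAGGTTGGAGCTATTGAGAAAACATGAGCGGATGTGGGAAGATATTTCTA
TGGGACACAGGGGCGCCGGGAGCTAAGATCCGCAAGGCACAGCCGACCTAGGCGATGTGCGTTAAAATGATGTGATTCCT
CCCAAAGTAAGAACATCTCCTGTGCAGGGACGATCGAGAGATTGGGCGTAGAGCGCTCCAGGAGCCCATAGGGAATAGGT
GGAAATGATCAGGGTGCTGAAG
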