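>locus
TATTCCTAACGAGCGTTTACGGGTTAGTTCTTGAAGTCGTAACTACACTTTTCGTATCAT
CAATGTTTACTGCAGTTTTTATGGGTTCTCTAGAACCGGGATACTGACATAGCTAACGAA
GACCCGCCGCCGTTTAAAGGATTTGGGACAATAACCTTAAATTTGATGTCCATGGAAATG
TATGGATAGATAGACCGAATGCAGCTGCGAGACCCTTGTCTAAAGAAATGAATAATATGC
CTCACCACAGTTCTCTCTCGATGTATATGCTCTGCCGGCTTCTGGCCTAGATTCGGTGGC
TATGCTCGCTTAATCTACCATATTCAGATGGTACGGTTCATCGTGCCGAGTTACTAATTC
GTGAGTATACTCTTGATCTTAATATACAGCGCCCCGTACTAAGCGAATAGTCTCGCCGCT
TCGGAGATCGTTCTTTGGGGTTAGATAACCATTCTCCATTGACCATCAATGGGGCCCGGG
ATGACATGTAATTTTCCACATACATCCGTACCTAACCCTAACGAGGACTCATCGGGCGAT
TCCCAGTCCAGTGATAATATCTCGCCGCAGCCGGGAGCTAGGACGCCGAACCACGAAGGG
CAACCGTACTTGTTCCTTCGAGATGAGCTTCATGGTTTGTGGCCTCCATGTTGCATGGCA
TTCTGGGCGGCGGAATAGGACATCTATACGACCGGCATTAGTCGCGCACTATAATCCCTC
CCAATATTTCACAGGCCGTCGCCCAAATAGCCGCTTCCCTGCCCGCGGCATGACTCCACG
TATGTATTGGGCTAAAACTGTATCTTCAGTCCGTACTGCTCATCAATCCCCACAGCGCTG
TTGATTATGCGCTGCGGCAAAACCTGACAGTTGTGCATGTCCTGCCCATAATGGCTCGAA
TTCCTTGCCCTCACCACAAAGGCTCGCGTTAAAACATGTGTGGCATGGAATGACGAGTTC
GCGTAAGTGTTAAGGGAGGGATTGTCTTAGGCGGGCGAGTGGGTACGTCCGGACGCACCA
CTTACATTGTCGGCAATTTTCTTTTTCGGAGATTTGTGTCTACGCCGCCGTCAGAGACCT
CGTGACTTGCCCCAACATCTTGCTAATTGACGATAGGCTGTTTGGCAGCTCTGCGAAGGC
GCAAAGGCCTCGTCTGTACTAATGCCAGAAGCTCGGCAAATATTGCACCGCGGCCGCGTG
ACGTCAGGCCCGGCGTACCGGTAACATGATTCTTCACGCCTTGTTTTTGATTGGTGGATA
AAAGTATTATTACCGCTTTACAGTGGATCCTGGTAGGGCGTATAAAGTCGGGGCGCAACG
CGACTCAGCGACCCCTATGAGCGTCTCTGAAGAAGTAGCTAATGGGTTATTACTTATCGT
ACATTCCGGTTATCGGAGTACGGGCTAGCGGAAGAAAAAAAAAACCGGTGTAAGCTTAAA
CAGCACGAACGTTTCGCAACAGAAGACGGGTACTCTTCAGACAATTATGAGTGTCTACAA
ACCGGTTGCATTCCCACCAAAGGATTCAGGGATGCGCTACGTAGCAAGGGCAGTCTAGTG
TTTAAAACACAGCAACAGTAAGGCACAATGACCGAATTTTATTGTTGCCACTGTTGTGTT
TGTTATCTAGTCAGGTAGGCGAGCAGATCCGAACCCAGAGTGTAATGGAAGGCGTCGTTC
TATCGGCGGGTCGGGAAATAAAACCCGGATGATTGCGCTTCGCAGTGTGTTTGACACGAT
AGCTTGATGTTCGATGTCCGCTGATCGCGGCTCTGCGATAAACGGAGGTAGTTATCGGAC
ATACTTAGTGATATAGAGCTCTTAGCCGCTTGGCTAATATAATGTTACGCACACAGCCCG
ACGACGTCTACAGTTGCAGACACGATATTGCGTTGCGGCTAGTCAGTCCTGCATGATGAT
TCCCGTAATCAACAAATTCTTCAGATACTAGAAGACTCGAGAACGTTGCGGACAAACACT
AGCACTTGCTGGCCGGGTGCGCTGATATGAGAAAGTCACGTAACTGAGGACAGTCTCCTA
ACATACAGGGTGCACCGCTCAAACTACAAAAACGGGGGCCGATAATGCCGACCGGAGCCT
AATTCCCTGCCAGGTGCTTTACACTTTCAGGTAGGCACACGTGTATCTATGGTATAAGAG
CACAGTGTTGATCACTCTAGAACGTCAGCAAAATGAGTCTGCAGGATGTCTGTCTATCGA
CTCCCACGGTCACGAAGCTACACAGGTGTGGTAGTGAAGGCACTGTGGTTTTTTGGAAGT
CCCCGCATAACTGGCTGAGCTCTACCCTCTTAGTCTTTTAGTAACCGAGTAGTAAATACG
CGCACCTCAACCATTACTAGCACAGGTTAGCATTCTAGCTCGCCCCGCGAGTTAGCAGAG
CGCTATGGACTCTTTAAGTTTTGTGACAGAATCCATCCCCATGCAATTAGAATGAGGAAA
ATGGGAACTAAACAGCGTTAATACTACCAAATGGTTCGTAGGGACCCATGTATCCGGCCC
TACTACGACCCGGGTGGCGTTAAAACTCCTTAGCAAGTCGGCCAAAGTTTGAGCATACCC
AGTCTACTTTGCGCATTATCGTTCATTAGGCAAAACCGCCCACGCTATGGGACTTTCTTG
GCTTGCTCCACGATACCAATCACATCGTCCTGCGGTAAGTCTAGCCCAGCCTAGGTGATA
GAACCAAGTCGCTCTCAGCGCCAGCCGATGTGCCAGTAGTCGCTGCTGATTGCTCTGCCA
CAGAACGCCCTACGTACACGAGAACTCTGACACAAATTTCGTCCATCTTCTAGTTGTGGC
GGGCAAGACTCAGCACCATCCAGTGGGAGGAGCTACCACACAAAATGGAACTCTCATAGC
ACTGAATTCATAGCAATTACCACAATCATAGTTAAAGGGATGCCCTGGAACCTATAGGTT
GCAACCGGATCTGATGCACCCGGACTAACGTCGAAGACGCGATCACCGTCCATGTTTGAT
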