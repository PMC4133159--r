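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
TATCGGCGGGTCGGGAAATAAAACCCGGAATTATAGTTTATCGGGGTCCAACCGAAGCTA
AAGCTTAGGGCGATGACCGAATATACTTGAGGCCACTTGGGCTGTACCGTACCTCGAAAT
TACCCGGACTGGGTATGCCTTGCTGCAAGCAAAAGCTGAAGCTGGGTTATGTGAAGCTCT
TTGCGGATTACTGACACTCCTGGACGCAAAAGTTCGATGATTGCGCTTCGCAGTGTGTTT
GACACGATAGCTTGATGTTCGATGTCCGCTGATCGCGGCTCTGCGATAAACGGAGGTAGT
TATCGGACATACTTAGTGATATAGAGCTCTTAGCCGCTTGGCTAATATAATGTTACGCAC
ACAGCCCGACGACGTCTACAGTTGCAGACACGATATTGCGTTGCGGCTAGTCAGTCCTGC
ATGATGATTCCCGTAATCAACAAATTCTTCAGATACTAGAAGACTCGAGAACGTTGCGGA
CAAACACTAGCACTTGCTGGCCGGGTGCGCTGATATGAGAAAGTCACGTAACTGAGGACA
GTCTCCTAACATACAGGGTGCACCGCTCAAACTACAAAAACGGGGGCCGATAATGCCGAC
CGGAGCCTAATTCCCTGCCAGGTGCTTTACACTTTCAGGTAGGCACACGTGTATCTATGG
TATAAGAGCACAGTGTTGATCACTCTAGAACGTCAGCAAAATGAGTCTGCAGGATGTCTG
TCTATCGACTCCCACGGTCACGAAGCTACACAGGTGTGGTAGTGAAGGCACTGTGGTTTT
TTGGAAGTCCCCGCATAACTGGCTGAGCTCTACCCTCTTAGTCTTTTAGTAACCGAGTAG
TAAATACGCGCACCTCAACCATTACTAGCACAGGTTAGCATTCTAGCTCGCCCCGCGAGT
TAGCAGAGCGCTATGGACTCTTTAAGTTTTGTGACAGAATCCATCCCCATGCAATTAGAA
TGAGGAAAATGGGAACTAAACAGCGTTAATACTACCAAATGGTTCGTAGGGACCCATGTA
TCCGGCCCTACTACGACCCGGGTGGCGTTAAAACTCCTTAGCAAGTCGGCCAAAGTTTGA
GCATACCCAGTCTACTTTGCGCATTATCGTTCATTAGGCAAAACCGCCCACGCTATGGGA
CTTTCTTGGCTTGCTCCACGATACCAATCACATCGTCCTGCGGTAAGTCTAGCCCAGCCT
AGGTGATAGAACCAAGTCGCTCTCAGCGCCAGCCGATGTGCCAGTAGTCGCTGCTGATTG
CTCTGCCACAGAACGCCCTACGTACACGAGAACTCTGACACAAATTTCGTCCATCTTCTA
GTTGTGGCGGGCAAGACTCAGCACCATCCAGTGGGAGGAGCTACCACACAAAATGGAACT
CTCATAGCACTGAATTCATAGCAATTACCACAATCATAGTTAAAGGGATGCCCTGGAACC
TATAGGTTGCAACCGGATCTGATGCACCCGGACTAACGTCGAAGACGCGATCACCGTCCA
TGTTTGAT
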