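>lys2_donor_synthetic homology region with 82 SNPs and inactivated cut site, synthetic stand-in
AAAACTCCATGTGTAACTCCGGAAGTAGAACCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTCCAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAAAGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCTGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCAGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTAGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGGCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGATAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGACCCTTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAAACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTCATAGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACTAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCTCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACATCGAGTACGTCGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACCTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCATTCGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGATGCGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTGATTGGTACGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCAAGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATCAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCAATGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACAACCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGCGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTACAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGATACCGTGAAGTGCCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACTCGGGCTTGCCAACCGGCAACGTGGCGTTGATTGACAGAGCTTCTTAAGCAGCTGATGTCCAAAAACTGAGTTAGTTCGAGATAGTTGGATGTCGCACTAGTGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACGTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGCTCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTATGGTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACCCGTTTCGCCTTAAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGACCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCACAGACGGATCCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGATCAACAGATATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGACCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTTCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGATTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATAAGGAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCAGCTAGGGATAACCATAACAGGGTAAAAGTATAGGACGCATACTCTGAAGTTCGAAGCGGTTCCTTATTGCTAATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTTCGCAGGGAAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCAGTGCGATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGAGGCACGGCATGGTGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATGCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTGTTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCAAACATATTTCTGCAAGATACTATTAGGTGGCTGGACTTGGGCTAGTGGCCGACTGCTACGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGGGAAAACCTTATTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGCCATCAACGAACGTGCGGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGCAGGACTGACAGTGTGAGCGCGAAGGTCGTGTCTTCGTTAGGCTGACGCACGATACCACGTCATACGCTATCATGAATCTTCCTTGCTGTTGGGCTAAGCGAGGATCGCTTACGAGGTTAAATCCCGCTCTTACAGGGAAGAGAGAGTCTTTCTTACTCGAGACCCATAGTACTATGATTTCGGGCAAAGAAGACGGGACCAATAATATTTGACGGCTCCAATCTCATGATCGTCCGGGGCATGCAGCCCTAGATCGTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGACACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGACGTCTCACAGGTTCATGCTGCAGGCTGGGTGCCGCTTACACACGCTAAGATAAAGACTTGCGCCAAAACGCTGGTGCTAAAAGAGCTTGTGATGCGTACGGGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTATAGCTTGTTTGCTTAATCCCGCCAAGTAAATAGCCCAGTCGGACGCGGCGTCCGCTAGATAACCGAACTATTCAACCTATCCAAATGTGGCCTAAAAGCGTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCACCGTGGAGCCGCATATTAAGAGTATACTATCGAGGAATTGCTGGATGGATACTATATTTGCAAAACAGCACTGTATTTGACGCCGCTATGGCCCTCGTGGGTGACATGCCGGGTTAGCTAGCCGGGCAACAACTCTTAGCGTTGAGTCGGGCTCAGAGTAGCACCCGTTGGCTGGGTTAAATATATCACACGGCAAGCGATGCGTCATGTGATAGGTGCGGAACTCCAGATTGGCGATGTGCAATTACTGTGCGACTTGTGATATCTACAGGGGACTCCAGAATATCACGTACTTCCCAATACCCAATATATTGCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAGCAGTTTACTGCGGAGAGAGAGCGCGAATCTATACTACGCTCCGTCTGGTTACCCTTGCCTGGTAAGAATGACTACGGCCTAGAATGGGTCCACACCCTGCCTCATAAAATTGCACTGAGCAGCAGAGCAACGAGTGACAAAGCTGGGAGCCCCCGATAGAAAGTACTGGATTTCTATGCCACATGGGACCGGCCAATACATCATGCTGGAATGTTCCAATGTTGCTTCGGGATCATCTATCTTGGGCGGATAACTTACGGGTACGTGCCTTGGCCGTCCTGCTCACGTGCTCGACGCTTACCGACTTAGCTAAGACGTGCGCTGAGGTTACTACGTCTGAAATTCCCCAGCGTTAGCAATTAAGACCGTTATGCCACTAGTGTAGCTTACTGATAATGACAGGTAGTAAAAAGTGCAATACCATCACGATCTATCATAGGTGTCATTGTAAAATCATGTCTATAAGACCTTTTCTGCTCTTGTACGGGTGCGATTAATACGTCTTCCGCTTAAAACCGCATCACAGCGTTGTTCTC
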