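>lys2_recipient_synthetic homology region, synthetic stand-in
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTGCCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGATAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGCCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGGTCAACAGATATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCGGCTAGGGATAACAGGGTAATAGTATAGGACGCATACTCTGAAGTTCGAAGCGGTTCCTTTTTGCTAATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTTCGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCAGTGGGATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGTGGCACGGCATGGTGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCAAACATATTGCTGCAAGATACTATTAGGTGGCTGGACTTGGGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGGGAAAACCTTAGTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGCCATCAACGATCGTGCGGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAAGGTCGTGTCTTCGTTAGGCTGACGCACTATACCACGTCATACGCTATCATGAATCTTCCTTGCTGTTGGGCTAAGCGGGGATCGCTTACGAGGTTAAATCCCGCTCTTACAGGGAAGAGAGAGTCTTCCTTACTCGAGACCCATAGTACTATGATTTCGGGCAAAGAAGACGGGACCACTAATATTTGACGGCTCCAATCTCATGATCGTCCGGGGCATGCAGCCCTACATCGTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGCCACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGAAGTCTCACAGGTTCATGCTGCAGGCTGGGTGCCGCTTACACACGCTAAGACAAAGACTTGCGCCAAAACGCTGGTGCTAAAAGAGCTTGTGATGCGTACGAGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTTTAGCTTGTTTGCTTAATCCCGCCAAGTAAATAGCCCAGTCGGACGCGGCTTCCGCTAGATAACCGAACTATTCAACCTATCCAAATGTGGCCTAAAAGCTTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCACCGTGGAGGCGCATATTAAGAGTATACTATCGAGGAATTGCTGGATGGATACTATATTTCCAAAACAGCACTGTATTTGACGCCGCTATGGCCCTCGTGGGTGACATGCTGGGTTAGCTAGCCGGGCAACAACTCTTAGCGTTGAGTCGGGCTCAGAGTTGCACCCGTTGGCTGGGTTAAATATATCACACGGCAAGCGATGCGTCATGTAATAGGTGCGGAACTCCAGATTGGCGATGTGCAATTACTGTGCGACTTGTCATATCTACAGGGGACTCCAGAATATCACGTACTTCCCAATACCCAATATCTTGCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAGCAGATTACTGCGGAGAGAGAGCGCGAATCTATACTACGCTCCGTCTGGTTACCGTTGCCTGGTAAGAATGACTACGGCCTAGAATGGGTCCACACCCTGCCTCCTAAAATTGCACTGAGCAGCAGAGCAACGAGTGACAAAGCTGGGAGCCCCCAATAGAAAGTACTGGATTTCTATGCCACATGGGACCGGCCAATACATCATTCTGGAATGTTCCAATGTTGCTTCGGGATCATCTATCTTGGGCGGATAACATACGGGTACGTGCCTTGGCCGTCCTGCTCACGTGCTCGACGCTTACCGACATAGCTAAGACGTGCGCTGAGGTTACTACGTCTGAAATTCCCCAGCGTTAACAATTAAGACCGTTATGCCACTAGTGTAGCTTACTGATAATGACAGGTACTAAAAAGTGCAATACCATCACGATCTATCATAGGTGTCATTGTAAAATCACGTCTATAAGACCTTTTCTGCTCTTGTACGGGTGCGATTAATACGTCTTCGGCTTAAAACCGCATCACAGCGTTGTTCTC
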