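>chr1
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATT
GCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCAC
ACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGC
TGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACT
CTGGCTTTAACCGTTGTGTCGTATGCTGCGCGAGAGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTC
CACACCAACGGCACAGCTAGGACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCAC
CGTACCCTAGAGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGTCGTCGATTTTTACATGACTG
AGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGTGGACACTGAAAAATCTAGTGTTCCGTCTCGTCCTCATATA
TGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACTACGACTTATTAGTAACAACAGGATTGTGAAACTTTAGGAA
GTTCTTATTTCAAAGCTGGTCTGAGACGAAATAGTCCTACCTTATCAAGAGTACTATAACGCGGTGATAAAGGGAGTTGC
ATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGGTCCTCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATG
AAGGCTTGTGAGGAGGGTCCTGGTGACATGTCTCATAACGCAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGC
CGCGGGAACATAGGCTTGTTTTATAATGACGGCTCGTGTAGGTTTATATCTGCCGCGTTAGGATCCTGTGCTAGGACGAG
AGAGAGAACAATGGCAGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
AAGTGGGTTCCCCCTATTTAACACTCGGGAGGAAGAGTTGGCAAATTGTGTTCCCTATGCGGCTACTACGGAGCCACGTG
TAGCACTGGGATGCTGGCGAACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACT
ACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTACTAC
TACTACTTAATTGTATTATGTTGTCGCGACCGAACCGACTAGATCCAGATGGACCAGCTAGGCAAACGTTGTACTGCGAC
ATGCCATGATGCACGGGTAAGCCCTACATATTGGTTCGCGCCTAGCTAAAAGCGAAAAACTCTTCCATAACGTCCTGCCC
AAGTGTCGCCCCATTGTTGGAGTACCATGTTGTGCTTGTGCGCCCACGAAAAGAATTGCCTGAGGAAACAGCACCTTAGT
TTGTGATTAGAGATTCCCTTCATGCGGGCTTTCATGGAGCTGTATTGATAGAAAGGGCTGTGAATCAGCTATCGTTAGGT
CCATTCTTCCATCATATCCAAAGTTCTACGACCGGGCCGTTCCGTAACTACCCTGCGGTAGCCAATCGTGGGGAGGCCTA
CATCGGCGTCTACCCCCTGCGTTGGTGATAGGCAAGAGCCCTTCATTCCGACCTCTCGGTACCCATAGTAAATGCTGCGG
TGTTACATATAGCGGCGAGTCCGGGCGTCCCGGATCAGTGTTAACCCGGGTGATGTACTTAAGTCTCGACTCTTCCCGGG
TATCAAGAGACTAGTCGTCGAGTATGTATCGGGCGAGGCTTTTGCCGATCCCTGGACACTAGCAATCGGGAAGCTCTTGC
ACGTTGGAAGAGGAAGCATCTTAAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGC
AGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAG
CAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCA
GCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCCAT
GGCATACATCTAAGACTTTTATTGTATTTTTCCCCGATGACACCCTTCAGCGACTAATGGCGCTAACCAGTTTGCATGAT
GTCGTACATTAGCGAATGGTGCCTTATCGCCTTGAAGACTGAAAATACATGTGAGAATCGGATAGTACCGAGAGCCTGCC
GATCACCCCGGACGTATAGGCTAAGTTCCCTTCGCAAAACCGCCCGTCATTATCTCTAAATTAATTCGAATTCAGCCGAG
TGTCTACCCACGACTATCAAACGTCTTTGCCCGGTCCACGTGCTGTGAAGCAGAAGTAGTATCTATTGATGGGACAAGAT
TTCGACATACAACCATCTACTGCGCGGCCTGCGCGTAAACGTATTATGCACGCACGATGCACTTGCAACTTAAATGGCTG
ACATTTAGCGGCCACTCATCGATCTCAGAGGGGCGCGGTGACGATGGAAACACTGAGAGTGTCGTATAGTAGGATGCAAC
CCTTCTATCCCGACCTGAACTTTGACCAACCCGCTGTTCCATTCCATCACATCCTGCAATTGACATTCCGCGCTGTCACG
ACCAAGGCGTCGTTCTGCTGTAGTCCTGCGGTAATGTGTT
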