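>KIR2DL1 synthetic CDS
ATGGTCGAGAAACTCTTTAACGAAAATTGTCACCCCTGGGGGCTCGTCAGTGTAAAGCACACGCGCCGTCCAGATAGCCGACGAAAGTGTGTAAACGGCGAATATCTCGGTCAGCAAATCAGGCTTTCGTGCACGCTAATACTAAGGGGCACGGCTTCTAGGCACACTGGCGCCGTTGAGTGTTCGCATATAACGTTCACACCTGTGCGAGGGAAAGTCCGCGGCAATTATGCTGAGTGCACGCGGCATAGATCGACATTCTTCGTCTTGGCTCCTAGGTTGACTTGTGGCGTCACCCAGACAAGCGCGCTGCCAATGCTCGAGTCTCTAACAAGATCCCCTAGTATGGCAATGGGGACCTCACTACCAAACGGCCACAAGCTCGCACTACCGTCGACCCGATGGGTAAGGCGTCCCTCTGCAGGTGGCAGTGGATTCCCGCACGTGCACAATCGGTGTCTGCCTATAGTCCTTGAACAGTACAATCTAAGAATGTCGTTGTGTTCTGGCGTCCCGTTTGGAACACAGCATCTCCGTTGGGAACTATACCTGAAAGAGGAATGGAGCTACAGAAGACAATACTTCCAGGATAAATACACATATTCAGGTCAACGCAAAGGAATCTGGGGCGGTCGCCAGTGTTCGGTAGTGGCTGTACACGTGGGTATGTCCAGGTGTGCCGAGACGTCTAAGGGCGGGGGCGTCCAGTTAGTGTATGAGTATCTGAACTTTTCGTCGGGTCCTGAGAGCGGAACTCTCTCACCTGAATTGCTGCGCCTTGGCCCGCCCGAGCACCGCCACGCGATGTGCCAGCTTTTGCATTGTGAAAAGAGTGAGCAGGCAAGTTGCCATGTAAAACTCAAACGTCTCTCCGTGAGCATGGTTACATCGAGAGGAAGGAGATATTGTTACGACGACCGGAACTGGTCTGTACCGACCAGGTTTCCTCGCGCCATCGTAACTACGGGTATGGAGACTCATCGAAATGGCAAAGTCGTAAATTATCGATCAGTGATTAGTGGGACGCGAGAACTGGTCCCGTACACTAGCAGA
>KIR3DL1S1 synthetic CDS
ATGGGAAGTACCTTTGACCATACGATTCTAAATGAAGTCAAGATCGGTACAGAAGCTCGCAGAATCAAGACCAGGCCGATCATCGGCGCCTGGTTGGTCGAGTATCTGCCAAACACATTACCTCTCCAATCGGCACAAGGGAAAGGGGTTCGCCTATCGGCAGTAACTCATGAGCATCCTGGCGGCTGGAATCAAGGTCGATTCGACGAACATGAAGGTGTAATCCGTGACGGAAATAGACTATTAACCAAGACAAAAGTAGATCGAAATGGACTCTTTAGCCCTGCCGGGACGCATCGTGTATACGAATGTAGCGAAATGGGGAACAATCAAGCAAGGATGTTACCAATCGCACCGCAGTTAGGCGCTGTCGCCTACATCACCACGCATCGGGAGAGCGAGCGCTCGTCTAAGTTTCGTCGAAACGGTTGGATCAACTATGCCGGCAAACCTTTGGGCCCCCGACGGTCTTTTAATAGATTCCCGACAAAACGGTCCAACCGGCTCTCCCCGTTAGTGTCTCCCGGGGTCTCTAGCACCGGAGCAGCCGGTCCTACCTCTATCGTCAAGGATTCCGAGGGGACAACTTATACTATCAGGGTGGGCTGGGACAGGCCAAGGTTGGGCCCAACCGTAGGCGTCCAAGACGTAATGATTGGCTCACTATACCCACGTCCTTCCGTGTCGTGCATCTTTAGCCTGCACTCAACCCGTTTCTGTGTGAGTCCCAACGCATCGGTAATAGGGTATCACCAGTTTGATGGTGTGGGACTTGTGGTTAATAGTAGGCATCACCTTCGGCACTTTAATATTCTTATCCAAGGGCCTGAGTGTCTACATGATAGTGGCAATGACCGGTCAACTGCTAGGAGCAAGCTCCCCACCTGTGAAAGCTATTCAGGCATTCCCAAGGGTTTGATTGCCCGTTTACGCCATCGCCGGAATACTTCACAGCCGATTGTAGTGCAGATCCCGGCTCCACGCAATGATGTAAGAGGCAGCAAATGTCACGCTGTGGCAACGATCCCAATGGTGTCGTGGAGGTCGTTGTCTAGTCCGCGGAGGGCCGAAGTAATCCTTCCTAAGTTTCGCATACACAGATTTTGTGACTTCAAACGCGGTGTCAAGATCTGGCAGGAGACGCAGGCGCACGTAGGTATGCAGCGCCAGCACTCCTCCTTTTCATCACGACGCCCCTCTAACGCCCATCTTTCCGGATCTAGATGTCGTGATCTTGCACCGCGGCGGAAATCATTCAAATTCAGGAAGACTCACATCTTCTGCAGAAGT
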