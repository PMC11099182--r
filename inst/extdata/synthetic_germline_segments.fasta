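>TOYHV1|IGH|V|75,24,51,24,114
CGGTCGTTCCGGACGAAAGGGGTAGGAACACATTTATAAAGCATTATGTAATAGGCACCGGGTGCCCTAGGTATGGCTCTGACCCA..AGACAGATATTCACGTACAGGTAGCCAGGGCGTTAATCGGCGCGCCATGTCTGGCTTAAGCAACTGCTCCGA...GCGTCTCCCGTACCTGGCGTTGCACAAGGGCCTACGTCCACTGCCTAAGGTCATCAATTGCCGTCTTCGTTGGCAATCTTACAACATAAATCTGCTAGTTTTTCAGGATCTCGGCTCCATTACCC
>TOYHV2|IGH|V|75,24,51,24,114
CATATTCTGACGTCCGTGACCTGGCCAGAGTACTGTATTCTGATTTGTTAAAGTATCACCTGCCAGGCGGGAAGTGCGTCGGGTTA.TCACTATCTCAGCCTCTGGTAGGAAATGTTACCCGGCATTAGAGCACGTTGTTACCATGAGTCGGAGTCACGGT..GGCACAACACGAACGTAGCGCGGAGCCGCCTGGGTACGGTGTATAAGCACACGACTGTCGGGCCTTCCTACGGTTTAACGAGCATCCTGGGGCGCCACTGAGGTTACTCTCAGTACTATGGCTCT
>TOYHV3|IGH|V|75,24,51,24,114
GGGTGTTAGTTTGGATTTTCGGCAACAATGGTGCGAACGACTGGATCCCGATCCCAGCTTCTGCTGGCACTGCTGCACACTTCT......CGATTAGAGGATACGTGATTCTACCTTAAGTGGCGCTGAGGAGGGTGTTCTGGTCCCCCTGAAGTTAACA...CATATCGCGGATGTTTCGGTTATTTAACCATGGTAGCCATGCCTTGAACACGGGCCTGGCTCACCCCTCGCGCGTATCTATTACCATCATGCAGCGCTGCATAGTTCCTAACTGGATCCAACATG
>TOYHV4|IGH|V|75,24,51,24,114
AAGCCGTGTAGCATAATAGAAGATAGCTCCGACGTCAAACACATGGTCAGCCCTATTAACTTCTGTCTCGGTCGTTTTTAAACTA...AAAGCCAGTAGTGGGGCATTCCGCCTCGGCAGCGGCTTATATCTGCTCCTTTAGGCGTGCGTGATTAAACTG...GGGAGTCGTTTGAGGCGTAGCGTCACGGATCAGTTGGTGCTCTTCGTGCTCGCAACGTCCAATAGAATCGACCCCGTCATCGATTGTACCGTGTTAGAGCAGCAAAAGTCACGCCCAACTCAAAG
>TOYHV5|IGH|V|75,24,51,24,114
GTCAATATGTATTACGACACAGGACAGCGCTAGATGTCCACGAAGACTTAGTTGTTCCCCCCGGGAGCCCGGTGCTCTTCGAGG.....GTGCGCACACTGCCCCGCGGCATATTGGGATAGCCCGGACGGGACTTGTTTGGGGAAAGAGGTGCCCGTCTT..AACGTGTATCTCTGTCACTGACACTCAAGTCTCGCGTTGCGTTAGACTCGCAGCTAAGGACCGTTAGTAGTTGTTTAAGAAACATTCCGGGTAGTTGCAAGTTATGTGGGTTTACATTTATTAGT
>TOYHV6|IGH|V|75,24,51,24,114
GGAGACAGTAAAATGCTAAAAAATAGCTTCTCCACTCCGACAAGGTCGCTAGCACAACGATTGGATTGGACGCCGTACGGTTGTGCGTTAAAGCCTCCATCCAGCACTTCCCACTACAGGCAGTACCGGGGGCCAGAAGTGTTCGACAAAAGGTGATTGCA.GAGCGTTCTGACAAGCGATAGCAGCAGATTAGCTGACTAATTCAGGTACTGCAGGTCGGGTCGTCGCGTAAGCCACTAAATTGCAAGTTCTTCCAGGTCGCACAGCGCCCCAGCAGAATACCACTA
>TOYHJ1|IGH|J|
TTCTCTCGGAATCCGCAAATAGTTCGTAAGCCAAGAGGTGCGGTCGGTGTTTAGTAAGTTATACTACCCGCCAATTGTGTCATACCCAAATGAGCAAGTTAGTATGGCCTGTACGCTGAACGCGCACACGGAGAATCCTCATATGTTTTGGCCATATCACCGTTA
>TOYHJ2|IGH|J|
GCAACTAACGGCCCTTGCTCCTTGCACGCTTTGTTGAATACAGGGGCGTAACAGGCCGGCGAAGGGTCTTGTTGTCACAGCCGTTACTTGCGACGATAATAAGGGAGTCCCTATGACCACGGAAGGTTAGTAGTTCGATGGTACTACTGTGC
>TOYHJ3|IGH|J|
TTCTCTTACACGCGCACCGGGAATCGTGAATCCAAGCCGATTACGCAAAACTGATTTCCAAGAGCAGCGCCGGCTGGACGATAACAAAGCAGGAAATGCTGCACTCCTCTTTCTGGGGCTCCTAGTTTTAAACGTATATACGAACCACGTTGGCGTTATAAACTTAGACCCGTAGATT
>TOYKV1|IGK|V|78,18,51,9,108
ATACGACCACACGGTACAAAAGATAAATCACCAGACATGCAATTTACTTAGGCCCCAATAGGAAGGGCGTGAAGTCGAGGGGTAC....TAACGTCAGTTCCGCACCCAGGGCGGGTTCCAGTACCAGAATGCTGTAACTAGTGACCCTCA.ATTCCACGCACTGAGGTGTGGGCCGTCACCGTCGGAGCTCAGTCCTCAGGACGCAGGAAGTACAAGGGTAGATCCAATCCGCGGCCTCTTAATGCGCATAAGGCGCTCCCAC
>TOYKV2|IGK|V|78,18,51,9,108
AAGGGACGCAGCTTTCGTCAGGGGTGAATCGTAGCGTACTCGCCGTCCGAGTTGCGGGTGTCGAAGAGTACGCCTGGGCTCCTCAA..AATTACTTCGACATGCTTCAGCTGAACAAACGTTCAGGGAGAACCGGGCGGCTCCATAAACCA.TTGTAGTTTTCCACAGGGAAGTGGGTCCATTCCGGGTCCAATTATCACAATTTCGGAGGAGGGACGATAAGGCTAGGTATATAGACCCAGGCTTGCGTCAAGTGGATAGCAG
>TOYKV3|IGK|V|78,18,51,9,108
CGCCTAACTCTCCAAAAGGCTGGAGTTTGATCCCGAGGAAAAGTCAGGCCTTCTTCCATTATGGATTAAACCCCTCGCTTTCACT...AGATACAAACTAGGACACGTTGGATACTCCGATAATGCCATACTTACCATAAATCTCACCAGC.AGTGGAGATACTTGGGCGAGTGTGGGGAGACAGTAAAACGCTGACTTCCACCAGGGGTGTTTTTGATTTCGGTTGCGAGGACTTTCGCCAATTTCGAAAAATGATCTCTTGG
>TOYKV4|IGK|V|78,18,51,9,108
CGTGAAATCTTTGCTCCTTCAAGGAGTTAAAGGTATTTTGAGTTCAACCTTGGAGCATAGGACGACCTAGGTCGCACCAGCACAG....TCGTCTGGATATCCTTTTACTTTCGATGCGAACGGTTTCGATTCTTGAACGCGTTTAGGTGGACTCAACCCTGCTGAACGACCCAGATCGTACGATTGATTCGTCACCCCTGGCGCGACTCACCTATGCTTACCCCTACAAAAGGCTCATCTCGCGCGCGACGCATACCAACTTC
>TOYKJ1|IGK|J|
ACTGATTCCGTGTACAGCAACCGGCGTACCTTGGTCGACGCAAGTGGGTCTCCATCATAAGTGTCCGATAGGGAAAGAAATATCGTTACAGTTCCAGTAGTAGTCAATCCGTGCGTATTTGGGACGAGTTAGGAGATATGCCGTTCGGTAATCTGA
>TOYKJ2|IGK|J|
GTTCAGGGGCCATGCTCAATGCCACGTCCTCATTTGCATAGTATTGTGGAGTGTCGCCTTGTTTGCTGGAATTTCATTTCCCTAGATGACACGATGCCACCACCCTAAGGCGGTTCTCAGTACTTAATTTACATTAACTGCCACAGCACCATTGCGCTAATGGCTCTACAA
>TOYKJ3|IGK|J|
GCGACCAGGCAAGTATTAGAATTGGGTACCGCCTGTTGCGGCACGATACTACTTTCATACAAAGTTTGGTTGCTGCACCTCTGCCCGACCAATGAGACCAGCAAACGGGGGGCGCGTCGGTTAAGGAGATCTACTTGATCCAAGAATGAGCGCCCGACTACATTATACGCAGAA
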