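>AluJ_syn synthetic Alu subfamily consensus (not a Repbase sequence)
TCACAGGAGAGAAATTAAGTCGCTTAATACGCGACTGATACGTCACTTCTACTGACCTAAGTGGGGGGGT
GATATAACCAGGCACTTACACGTGAGGTAATACACATACGTACGACTGAAAGCGTCCGAGTCGATACCTG
CGAGAAGGGTTACTCTATTGTTTTTACCATGAATCTAACCCTCAGCAGCTTGCAAGCGCACTCGAGTTAA
TATACCCAGATGGACATGATCATTCAGTACGGGATTTTCGCAGACTGGACAGGACCATCCCCGCCTGTCG
ATCCCCTACTTCAACTATTT
>AluSx_syn synthetic Alu subfamily consensus (not a Repbase sequence)
TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGAGCCGTCATTTCTTCAGACCTAAGTGTGTGGGG
GATCTACCCAAGCACATACCTGTGAGGTAATTCAGATACGAACGACTAAGGGCGACCGAGTCACTACCTG
CGAGATTGGTTACTCGTATCTGTTTCCTATCGCCTTCATCCTGAAAAGACAGCATGTGCTCTGGGGGTAA
TATACCCAGATCGTAATTCTCATTCAGAATGGGTTTTACGCGGACCGGACAGTACCCTCCCGCCCAGTAG
GGCCCCTACCTAAACTAATT
>AluSz_syn synthetic Alu subfamily consensus (not a Repbase sequence)
TCTCAGGAGCGATGTTATGTCACTTAATACGTGACTGCTCCGTCATTTCTACAGACCTAAGTGGGTTGGG
TATCTCCCCCGGCACCTACCTGTGAGGAAATTCAGTTACATGCTACTAACGGCGAACGAGCCACTAGCTG
CGAGATTGGTTACTCGTTTATGTTTCCTATCTTCCTCAACCTGAAAAGCGAGCATGGGCTCTGAAGTTAA
TATACACAGATCGTAATTTTCATTCAGAACGGAATTCACTCGGACCGGACAGGACCATCCTGGCCAGTAG
GGCCCCTACCTAAACTAATT
>AluY_syn synthetic Alu subfamily consensus (not a Repbase sequence)
TCTCAGGAGCGATATTTTGTCACTTAATACGTGACTGATCCGTCATTTCATCAGAGCGACGTGGGTGGGG
GATCTACCCAGGCACATACCTGTGAGGTACTTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTG
CCAGATTGGTTACTCGTTTGTGTTTCCTATCGTCCTCAACCTGAAAAACCAGCATCCGCTCTGGAGATAA
TATACCCAGATCGTAATTCTCATTCAGAAAGGGATTTATACGGCCCGGACTGGACCATCCCGGCCAGTAG
GGCCCTTACCTAAACTAATT
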