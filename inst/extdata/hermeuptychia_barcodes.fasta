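>KJ025561|Hermeuptychia sosybius
AACTTTATATTTTATTTTTGGTATTTGAGCAGGAATAATTGGAACATCATTAAGTTTAAT
TATCCGAATAGAATTAGGTAACCCAGGATTTTTAATTGGAGATGACCAAATTTATAATAC
TATTGTTACAGCTCATGCTTTTATTATAATTTTTTTTATAGTAATACCTATTATAATTGG
AGGATTTGGTAATTGACTTATTCCTTTAATATTAGGAGCTCCTGATATAGCTTTTCCGCG
TATAAATAATATAAGATTTTGATTATTACCTCCATCTTTAATTTTATTAATTTCTAGCAG
TATTGTAGAAAATGGAAGTGGAACAGGATGAACTGTTTACCCCCCTCTTTCATCTAATAT
TGCTCATAGAGGTTCTTCAGTAGATTTAGCAATTTTTTCTCTTCATTTAGCTGGAATTTC
ATCAATTTTAGGAGCTATTAATTTTATTACAACAATTATTAATATACGAATTAATAATAT
ATCTTATGATCAAATACCTTTATTTATTTGAGCTGTAGGAATTACTGCTCTTCTTTTACT
TCTCTCATTACCTGTTTTAGCAGGAGCTATTACCATACTTCTTACTGATCGAAATTTAAA
TACATCATTTTTTGATCCTGCAGGAGGAGGAGATCCTATTTTATATCAACATTTATTT
>KJ025595|Hermeuptychia intricata
AACTTTATATTTTATTTTTGGTATTTGAGCAGGAATAATTGGTACATCATTAAGTTTAAT
TATCCGAATAGAATTAGGTAATCCAGGATTTTTAATTGGAGATGACCAAATTTATAATAC
TATTGTTACAGCTCATGCTTTTATTATAATTTTTTTTATAGTAATACCCATTATAATTGG
AGGATTTGGTAATTGACTTGTCCCTTTAATATTAGGAGCTCCTGATATAGCTTTCCCACG
TATAAATAATATAAGATTTTGATTATTACCCCCATCTTTAATTTTATTAATTTCTAGTAG
TATTGTAGAAAATGGAAGTGGGACAGGATGAACAGTTTACCCCCCCCTCTCATCTAATAT
TGCTCATAGAGGTTCTTCAGTAGATTTAACAATTTTTTCACTTCATTTAGCTGGAATTTC
TTCAATCTTAGGAGCTATTAATTTTATTACAACAATTATTAACATACGAATCAATAATAT
ATCTTATGATCAAATACCTTTATTTATTTGAGCTGTAGGAATTACAGCTCTTCTTTTACT
TCTTTCATTACCTGTTTTAGCAGGAGCTATTACTATACTTCTTACTGATCGAAATTTAAA
TACATCATTTTTTGATCCTGCAGGAGGAGGAGATCCTATTTTATATCAACATTTATTT
>KJ025569|Hermeuptychia hermybius
AACTTTATATTTTATTTTTGGTATTTGAGCAGGAATAATTGGAACATCATTAAGTTTAAT
TATTCGAATAGAGTTAGGTAATCCAGGATTTTTAATTGGAGATGACCAAATTTATAACAC
TATTGTTACAGCCCATGCTTTTATTATAATTTTTTTTATAGTAATACCTATTATAATTGG
AGGATTTGGTAATTGACTTATTCCTTTAATATTAGGAGCTCCTGATATAGCTTTCCCACG
TATAAATAATATAAGATTTTGATTATTACCCCCATCTTTAATTTTATTAATTTCTAGTAG
TATTGTAGAAAATGGAAGTGGAACAGGATGAACTGTTTACCCCCCTCTTTCATCTAATAT
TGCCCATAGAGGTTCTTCAGTAGATTTAGCAATTTTTTCTCTTCATTTAGCTGGAATTTC
ATCAATTTTAGGAGCCATTAATTTTATTACAACAATTATTAATATACGAATTAATAATAT
ATCTTATGATCAAATACCTTTATTTATTTGAGCTGTAGGAATTACAGCTCTTCTTTTACT
TCTCTCATTACCTGTTTTAGCAGGAGCTATTACCATACTTCTTACTGATCGAAATTTAAA
TACATCATTTTTTGACCCTGCAGGAGGAGGAGATCCTATTTTATATCAACATTTATTT
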