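>synthetic_rnasep_like 325 nt synthetic stand-in; cassettes 1-14 and 283-325
TAGAATAGGCTTTATTACAGTCTGATGAAAAAGGAGATTTTCGCCGACCCGTGTCGACTA
CTCAATAAAGGCCTGTATAATACATACCGGTATCCAATGCACAAAGTTGTTACTAATTTC
GCCTCCTGGTAGATGGTCTGAGAAACGTAATACCCGTGTTCGAGGGAGGTCCTTCAAAAA
ACACTTGAGAGTCGAAGAGCTTCCCTTACTAGTCTACGAATTTAAATTATTTTCCCAAAC
AGATAATCGTACAAGGAAATGAGCCTGGGAGTGCAGTACTCTTCCTGAGAGGCATCCCGA
ATAGTCTGCGTTATCCTAAAAAGGA
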