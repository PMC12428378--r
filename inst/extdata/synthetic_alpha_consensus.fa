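>synthetic_alpha_consensus 171 bp synthetic stand-in for an alpha-satellite consensus monomer
AGTGCAAACATTAGGTCAGGGGACTTCCGGCAAATTACAATAGTACACATAGTTCTAGAG
AATTGACTGGTAATCTTCATGATTGTTATATTATGCGAAGTACTTAATTGAAATCTACCA
ATGGGCTAGATGTAAAGATTCTGTGTTTCAGCTAACAACTAATTATCGGTT
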