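LOCUS       SYN00001                 120 bp    DNA     linear   SYN 01-JAN-2026
DEFINITION  Synthetic example clone 1, partial exon1-intron-exon2 amplicon
            (synthetic fixture, not a deposited sequence).
ACCESSION   SYN00001
VERSION     SYN00001.1
SOURCE      synthetic construct
ORIGIN
        1 atggctaaac cagtaagtct tgacctgaca gattacagtt ctctagcagg attcgtcgca
       61 tggctgaaat ccgtacctgg agatttcaaa gcaggtgcag acctcgaagc taaatga
//
LOCUS       SYN00002                  90 bp    DNA     linear   SYN 01-JAN-2026
DEFINITION  Synthetic example clone 2 (synthetic fixture).
ACCESSION   SYN00002
VERSION     SYN00002.1
SOURCE      synthetic construct
ORIGIN
        1 atggctaaac cagtaagtct tgacctgaca gattacagtt ctctagcagg attcgtcgca
       61 tggctgaaat ccgtacctgg agatttcaaa
//
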