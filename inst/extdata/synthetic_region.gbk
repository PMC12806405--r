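LOCUS       ctg_demo_1               720 bp    DNA     linear   BCT 01-JAN-2026
DEFINITION  synthetic demo contig region.
ACCESSION   ctg_demo_1
FEATURES             Location/Qualifiers
     region          1..720
                     /region_number="1"
                     /product="thiopeptide"
     CDS             1..240
                     /locus_tag="demo_001"
                     /gene_functions="biosynthetic (rule-based-clusters) thiopeptide:
                     Lant_dehydr_N"
     CDS             complement(241..480)
                     /locus_tag="demo_002"
                     /gene_functions="biosynthetic (rule-based-clusters) thiopeptide:
                     YcaO"
     CDS             481..720
                     /locus_tag="demo_003"
                     /gene_functions="transport (smcogs) SMCOG1000: ABC transporter"
ORIGIN
        1 aaaactccat gtgtaactcc ggaagtagaa tcttgcactc ggcctttcca tatctcgtga
       61 accccctgca cgccctaaag tacaattagg atattcatcc ctacactgta tatgccgaac
      121 gttctaataa acgacttagc aacaagtcgc ctagaaaggt accgctggca tatcacgcct
      181 cccgcttgcc gtcttcaact tcatgaccct cgtgcatcac aaagcctcaa gccggagtct
      241 aggctttgaa acagctgaat aaatcgtgtg aatacgtgag tcgtcggaaa gcagttgaat
      301 atctaacgac ccctgcgcaa ggacacacta gtcgcccttg agagcactcc agtccaggcg
      361 aggtatccac gacgatacga ctcggctagc aaacgcgcgg tttatctatg cagctaatat
      421 ccttagtagt cgacccctga gatgaccggt catcaggcgg catccgacgc accaacggct
      481 cctacagact cgtgctaccg gaccatgcga ctcgaacatc agatggacag acctcgtaat
      541 agccgggcca tgtaacactg atgtctccgg gcagctcatg acgagcacca gacccgagag
      601 ttcctgttag ttttggttag gcacggaacg ctatcgagcg cgtaagcgcc aacccgcatt
      661 tacgaagtac ccatcgtatg taataagacc tcgagtacgt cgggacgttg gctgtgatgt
//
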