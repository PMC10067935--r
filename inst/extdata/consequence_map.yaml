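# Controlled vocabulary: variant consequence term -> functional category
# and super-group. Edit and pass to categorize_snps(vocabulary = ...).
intergenic_variant:
  category: intergenic
  group: non-coding
intron_variant:
  category: intron
  group: non-coding
lncRNA_variant:
  category: lncRNA
  group: ncRNA
miRNA_variant:
  category: miRNA
  group: ncRNA
TF_binding_site_variant:
  category: TFBS
  group: regulatory
promoter_variant:
  category: promoter
  group: regulatory
enhancer_variant:
  category: enhancer
  group: regulatory
repressor_variant:
  category: repressor
  group: regulatory
promoter_flanking_region_variant:
  category: promoter-flanking
  group: regulatory
open_chromatin_variant:
  category: open-chromatin
  group: regulatory
5_prime_UTR_variant:
  category: 5'UTR
  group: coding
3_prime_UTR_variant:
  category: 3'UTR
  group: coding
synonymous_variant:
  category: synonymous
  group: coding
missense_variant:
  category: nonsynonymous-missense
  group: coding
stop_gained:
  category: nonsense
  group: coding
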