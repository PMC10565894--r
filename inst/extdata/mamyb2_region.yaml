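# Worked-example locus: the MaMyb2 flower-color gene region of the
# Mimulus aurantiacus reference assembly. Coordinates are 1-based inclusive.
locus: MaMyb2
chromosome: "4"
gene_start: 12317113
gene_end: 12318500
focal_snp: 12317808
ehh:
  core_alleles: [0, 1]
  cutoff: 0.05
scan:
  window_size: 10000
  window_step: 100
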