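#' Coordinates of the MaMyb2 worked-example region
#'
#' Returns the bundled configuration for the flower-color locus used as the
#' package's worked example: the *MaMyb2* gene on chromosome 4 of the
#' *Mimulus aurantiacus* reference (positions 12,317,113--12,318,500, focal
#' SNP 12,317,808), together with the scan settings appropriate for a
#' gene-scale analysis (10 kb windows sliding by 100 bp).
#'
#' @return A named list: `locus`, `chromosome`, `gene_start`, `gene_end`,
#'   `focal_snp`, `ehh` (core alleles and cutoff) and `scan` (window
#'   size/step).
#' @export
mamyb2_region <- function() {
  yaml::read_yaml(system.file("extdata", "mamyb2_region.yaml",
                              package = "introscan"))
}
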