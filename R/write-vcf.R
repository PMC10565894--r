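#' Write a genotype matrix as a VCF 4.2 fixture
#'
#' Emits a minimal, deterministic VCF with `##contig` header lines so that
#' [read_vcf()] round-trips genotypes exactly. Invariant sites are written as
#' `ALT = "."` records. When a phased [hap_panel()] covering the same sites
#' is supplied, genotypes are written phased (`a|b`) from the haplotype
#' pairs; otherwise unphased diploid genotypes are derived from the allele
#' counts (`0/0`, `0/1`, `1/1`, or `./.` for missing calls).
#'
#' @param gm A [geno_matrix()] with diploid entries (called 0 or 2).
#' @param path Output path (plain text).
#' @param panel Optional [hap_panel()] whose consecutive row pairs match
#'   `gm$samples` and whose positions match the variant sites of `gm`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, panel = NULL) {
  lens <- attr(gm, "contig_lengths")
  if (is.null(lens)) {
    lens <- vapply(split(gm$pos, gm$contig), max, integer(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )

  n <- length(gm$pos)
  if (!is.null(panel)) {
    if (ncol(panel$haplotypes) != n ||
        !all(panel$positions == gm$pos)) {
      stop("panel sites do not match the genotype matrix")
    }
    odd <- panel$haplotypes[seq(1, nrow(panel$haplotypes), 2), , drop = FALSE]
    evn <- panel$haplotypes[seq(2, nrow(panel$haplotypes), 2), , drop = FALSE]
    gt <- matrix(paste0(t(odd), "|", t(evn)), nrow = n)
  } else {
    code <- function(called, alt) {
      out <- rep("./.", length(called))
      out[called == 2 & alt == 0] <- "0/0"
      out[called == 2 & alt == 1] <- "0/1"
      out[called == 2 & alt == 2] <- "1/1"
      out[called == 1 & alt == 0] <- "0"
      out[called == 1 & alt == 1] <- "1"
      out
    }
    gt <- vapply(seq_along(gm$samples), function(j) {
      code(gm$called[, j], gm$alt_count[, j])
    }, character(n))
    if (n == 1) gt <- matrix(gt, nrow = 1)
  }

  body <- if (n == 0) character(0) else paste(
    gm$contig, gm$pos, ".", gm$ref,
    ifelse(is.na(gm$alt), ".", gm$alt), ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
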