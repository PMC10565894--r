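#' Construct a genotype matrix
#'
#' The shared substrate of every statistic in the package: per-site allele
#' counts for all samples on one or more contigs, with explicit support for
#' missing genotypes (represented as called-allele deficits, never imputed)
#' and for invariant sites (which contribute only to the denominators of
#' pi and d_xy).
#'
#' @param contig Character vector, contig id per site.
#' @param pos Integer vector of 1-based positions (VCF convention), strictly
#'   increasing within each contig.
#' @param ref,alt Character vectors of reference/alternate alleles; invariant
#'   sites carry `NA` alt.
#' @param called Integer matrix (sites x samples) of called allele counts
#'   (0--2 for diploids; haploid columns permitted).
#' @param alt_count Integer matrix (sites x samples) of alternate-allele
#'   counts, each entry at most the corresponding `called` entry.
#' @param is_variant Logical vector flagging sites with a segregating
#'   alternate allele. Defaults to `!is.na(alt)`.
#' @param samples Character vector of sample names (defaults to the column
#'   names of `called`).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(contig, pos, ref, alt, called, alt_count,
                        is_variant = !is.na(alt), samples = colnames(called)) {
  called <- as.matrix(called)
  alt_count <- as.matrix(alt_count)
  storage.mode(called) <- "integer"
  storage.mode(alt_count) <- "integer"
  n <- length(pos)
  stopifnot(
    length(contig) == n, length(ref) == n, length(alt) == n,
    nrow(called) == n, nrow(alt_count) == n,
    ncol(called) == ncol(alt_count)
  )
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(called)))
  if (any(alt_count > called)) {
    stop("alt_count exceeds called count at ", sum(alt_count > called), " cell(s)")
  }
  for (ctg in unique(contig)) {
    p <- pos[contig == ctg]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on contig ", ctg)
    }
  }
  inv <- !is_variant
  if (any(inv) && any(alt_count[inv, , drop = FALSE] > 0)) {
    stop("invariant sites must have zero alt counts")
  }
  colnames(called) <- colnames(alt_count) <- samples
  structure(
    list(
      contig = as.character(contig), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      is_variant = as.logical(is_variant),
      called = called, alt_count = alt_count, samples = samples
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d sites (%d variant) x %d samples on %d contig(s)\n",
    length(x$pos), sum(x$is_variant), length(x$samples),
    length(unique(x$contig))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$pos), length(x$samples))

#' Coerce a genotype matrix to a tidy site table
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per site and the per-sample alt counts as
#'   columns.
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      contig = x$contig, pos = x$pos, ref = x$ref, alt = x$alt,
      is_variant = x$is_variant
    ),
    tibble::as_tibble(x$alt_count)
  )
}

# subset sites by logical/integer index
gm_subset <- function(gm, idx) {
  geno_matrix(
    contig = gm$contig[idx], pos = gm$pos[idx],
    ref = gm$ref[idx], alt = gm$alt[idx],
    called = gm$called[idx, , drop = FALSE],
    alt_count = gm$alt_count[idx, , drop = FALSE],
    is_variant = gm$is_variant[idx], samples = gm$samples
  )
}

# per-population called/alt allele-count vectors (sites x 1 per pop)
pop_counts <- function(gm, popmap, pops) {
  out <- lapply(pops, function(p) {
    s <- popmap$sample[popmap$population == p]
    missing <- setdiff(s, gm$samples)
    if (length(s) == 0) stop("population '", p, "' has no samples in the map")
    if (length(missing) > 0) {
      stop("samples absent from genotype matrix: ", paste(missing, collapse = ", "))
    }
    list(
      called = rowSums(gm$called[, s, drop = FALSE]),
      alt = rowSums(gm$alt_count[, s, drop = FALSE])
    )
  })
  names(out) <- pops
  out
}
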