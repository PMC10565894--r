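#' Read a VCF into a genotype matrix
#'
#' Applies the biallelic-SNP filter used throughout the package: multiallelic
#' records and non-SNP alleles are dropped; optionally, sites with any missing
#' genotype are removed, and invariant (homozygous-reference, `ALT = "."`)
#' records are retained for invariant-site-aware pi/d_xy denominators.
#' Half-calls such as `0/.` are treated as fully missing.
#'
#' @param path Path to a VCF or bgzipped VCF with GT fields.
#' @param region Optional `"contig:start-end"` string (1-based inclusive).
#' @param keep_invariant Keep `ALT = "."` records, flagged `is_variant = FALSE`?
#' @param require_complete Drop sites with any missing genotype?
#'
#' @return A [geno_matrix()] with attributes `n_records_read` and
#'   `n_records_kept`, and `contig_lengths` taken from `##contig` header lines
#'   (falling back to the last observed position, with a warning).
#' @export
read_vcf <- function(path, region = NULL, keep_invariant = FALSE,
                     require_complete = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_read <- nrow(fix)
  if (is.null(n_read) || n_read == 0) stop("VCF contains no records: ", path)

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  contig_lengths <- vcf_contig_lengths(vcf, chrom, pos)

  keep <- rep(TRUE, n_read)
  if (!is.null(region)) {
    reg <- parse_region(region)
    if (!reg$contig %in% chrom) {
      stop("region contig '", reg$contig, "' absent from VCF")
    }
    keep <- keep & chrom == reg$contig & pos >= reg$start & pos <= reg$end
  }

  invariant <- is.na(alt) | alt == "." | alt == ""
  snp_ref <- !is.na(ref) & ref %in% c("A", "C", "G", "T")
  snp_alt <- !invariant & !is.na(alt) & alt %in% c("A", "C", "G", "T")
  keep <- keep & snp_ref & (snp_alt | (invariant & keep_invariant))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  gt <- gt[keep, , drop = FALSE]
  parsed <- parse_gt(gt)

  if (require_complete) {
    ploidy <- max(parsed$called, 1L)
    complete <- rowSums(parsed$called == ploidy) == ncol(gt)
    idx <- which(keep)[complete]
    parsed$called <- parsed$called[complete, , drop = FALSE]
    parsed$alt <- parsed$alt[complete, , drop = FALSE]
  } else {
    idx <- which(keep)
  }

  inv_kept <- invariant[idx]
  gm <- geno_matrix(
    contig = chrom[idx], pos = pos[idx], ref = ref[idx],
    alt = ifelse(inv_kept, NA_character_, alt[idx]),
    called = parsed$called, alt_count = parsed$alt,
    is_variant = !inv_kept, samples = samples
  )
  attr(gm, "n_records_read") <- n_read
  attr(gm, "n_records_kept") <- length(idx)
  attr(gm, "contig_lengths") <- contig_lengths
  gm
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region '", region, "'; expected contig:start-end")
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

vcf_contig_lengths <- function(vcf, chrom, pos) {
  meta <- vcf@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", ctg)))
  out <- stats::setNames(lens[!is.na(lens)], ids[!is.na(lens)])
  seen <- unique(chrom)
  absent <- setdiff(seen, names(out))
  if (length(absent) > 0) {
    warning(
      "no ##contig length for: ", paste(absent, collapse = ", "),
      "; using last observed position"
    )
    last <- vapply(absent, function(ctg) max(pos[chrom == ctg]), integer(1))
    out <- c(out, stats::setNames(last, absent))
  }
  out
}

# GT strings -> called / alt count matrices; any "." in a call marks the
# whole call missing (half-calls are fully missing)
parse_gt <- function(gt) {
  u <- unique(as.vector(gt))
  n_alleles <- function(g) nchar(gsub("[^01]", "", g))
  lookup_called <- ifelse(is.na(u) | grepl("\\.", u), 0L, n_alleles(u))
  lookup_alt <- ifelse(lookup_called > 0L, nchar(gsub("[^1]", "", u)), 0L)
  i <- match(gt, u)
  called <- matrix(lookup_called[i], nrow(gt), ncol(gt))
  alt <- matrix(lookup_alt[i], nrow(gt), ncol(gt))
  colnames(called) <- colnames(alt) <- colnames(gt)
  list(called = called, alt = alt)
}

#' Read a sample-to-population map
#'
#' Two-column whitespace/tab separated file (sample, population); an optional
#' first line starting with `#` is treated as a header and skipped. Population
#' order is order of first appearance.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `sample` and `population`; the population
#'   order is stored in `attr(, "populations")`.
#' @export
read_population_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && startsWith(lines[1], "#")) lines <- lines[-1]
  if (length(lines) == 0) stop("empty population map: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed population map line: ", lines[which(bad)[1]])
  samples <- vapply(parts, `[`, character(1), 1)
  pops <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in population map: ",
         samples[duplicated(samples)][1])
  }
  population_map(samples, pops)
}

#' Build a population map from vectors
#'
#' @param samples Character vector of sample ids.
#' @param populations Character vector of population labels, parallel to
#'   `samples`.
#' @return A tibble as from [read_population_map()].
#' @export
population_map <- function(samples, populations) {
  out <- tibble::tibble(sample = samples, population = populations)
  attr(out, "populations") <- unique(populations)
  out
}

#' Extract phased haplotypes from a VCF region
#'
#' Requires fully phased (`|`) complete genotypes at biallelic SNPs; a diploid
#' sample contributes two haplotype rows. Errors on any unphased or missing
#' genotype inside the region.
#'
#' @param path VCF path.
#' @param region `"contig:start-end"` (1-based inclusive).
#' @param samples Character vector of samples to extract.
#' @param popmap Optional population map used to label haplotypes.
#' @return A [hap_panel()].
#' @export
extract_haplotypes <- function(path, region, samples, popmap = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  reg <- parse_region(region)
  if (!reg$contig %in% chrom) stop("region contig '", reg$contig, "' absent from VCF")
  keep <- chrom == reg$contig & pos >= reg$start & pos <= reg$end &
    ref %in% c("A", "C", "G", "T") & !is.na(alt) & alt %in% c("A", "C", "G", "T")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  absent <- setdiff(samples, colnames(gt))
  if (length(absent) > 0) stop("samples absent from VCF: ", paste(absent, collapse = ", "))
  gt <- gt[keep, samples, drop = FALSE]

  if (any(is.na(gt)) || any(grepl("\\.", gt))) {
    stop("missing genotype encountered in phased region")
  }
  if (nrow(gt) > 0 && any(!grepl("|", gt, fixed = TRUE))) {
    stop("unphased genotype encountered: ", gt[!grepl("|", gt, fixed = TRUE)][1])
  }

  n_hap <- 2L * length(samples)
  H <- matrix(0L, n_hap, nrow(gt))
  for (j in seq_along(samples)) {
    al <- strsplit(gt[, j], "|", fixed = TRUE)
    H[2L * j - 1L, ] <- as.integer(vapply(al, `[`, character(1), 1))
    H[2L * j, ] <- as.integer(vapply(al, `[`, character(1), 2))
  }
  meta <- tibble::tibble(
    haplotype = paste0(rep(samples, each = 2), "_", rep(1:2, length(samples))),
    sample = rep(samples, each = 2)
  )
  if (!is.null(popmap)) {
    meta$population <- popmap$population[match(meta$sample, popmap$sample)]
  }
  hap_panel(H, positions = pos[keep], meta = meta)
}

#' Construct a phased haplotype panel
#'
#' @param haplotypes Integer 0/1 matrix, haplotypes x sites, no missing data.
#' @param positions Integer site positions, strictly increasing.
#' @param meta Optional tibble with one row per haplotype (`haplotype`,
#'   `sample`, `population`).
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haplotypes, positions, meta = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  stopifnot(ncol(haplotypes) == length(positions))
  if (length(positions) > 1 && is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (nrow(haplotypes) > 0 && ncol(haplotypes) > 0 &&
      !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1")
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(haplotype = paste0("hap_", seq_len(nrow(haplotypes))))
  }
  structure(
    list(haplotypes = haplotypes, positions = as.integer(positions), meta = meta),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d sites\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$haplotypes)

#' Collapse a haplotype panel to diploid genotype counts
#'
#' Inverse of phasing: consecutive haplotype pairs are summed into per-sample
#' alternate-allele counts, yielding the genotype matrix for the same region.
#'
#' @param panel A [hap_panel()] whose rows pair up as `sample_1`, `sample_2`.
#' @param contig Contig label for the resulting sites.
#' @return A [geno_matrix()].
#' @export
collapse_haplotypes <- function(panel, contig = "chr") {
  n_hap <- nrow(panel$haplotypes)
  if (n_hap %% 2L != 0L) stop("odd number of haplotypes; cannot pair into diploids")
  n <- n_hap / 2L
  alt <- panel$haplotypes[seq(1, n_hap, by = 2), , drop = FALSE] +
    panel$haplotypes[seq(2, n_hap, by = 2), , drop = FALSE]
  samples <- if ("sample" %in% names(panel$meta)) {
    unique(panel$meta$sample)
  } else {
    paste0("S", seq_len(n))
  }
  alt <- t(alt)
  variant <- rowSums(alt) > 0
  geno_matrix(
    contig = rep(contig, length(panel$positions)), pos = panel$positions,
    ref = rep("A", length(panel$positions)),
    alt = ifelse(variant, "T", NA_character_),
    called = matrix(2L, length(panel$positions), n),
    alt_count = alt, is_variant = variant, samples = samples
  )
}
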