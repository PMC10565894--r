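# Independent brute-force oracles used to validate the package's statistics.
# These deliberately avoid the package's own kernels: everything is literal
# enumeration over alleles, pairs, patterns or spanning trees.

# --- literal ABBA/BABA pattern counting on haploid 0/1 matrices -------------
# mat: sites x 4 (P1, P2, P3, outgroup), entries 0/1 (alt allele). The derived
# allele at a site is the one NOT carried by the outgroup.
count_d_oracle <- function(mat) {
  abba <- 0L
  baba <- 0L
  for (i in seq_len(nrow(mat))) {
    g <- mat[i, ]
    derived <- 1L - g[4]  # polarize: outgroup carries the ancestral allele
    b <- as.integer(g == derived)
    if (b[1] == 0 && b[2] == 1 && b[3] == 1) abba <- abba + 1L
    if (b[1] == 1 && b[2] == 0 && b[3] == 1) baba <- baba + 1L
  }
  if (abba + baba == 0) return(NA_real_)
  (abba - baba) / (abba + baba)
}

# --- pair enumeration for pi / dxy / FST ------------------------------------
# expand one site's per-sample (called, alt) into a literal allele vector
site_alleles <- function(called, alt) {
  unlist(mapply(function(k, a) c(rep(1L, a), rep(0L, k - a)),
                called, alt, SIMPLIFY = FALSE))
}

pi_oracle <- function(called_mat, alt_mat) {
  n_diff <- 0
  n_comp <- 0
  for (i in seq_len(nrow(called_mat))) {
    al <- site_alleles(called_mat[i, ], alt_mat[i, ])
    k <- length(al)
    if (k < 2) next
    for (x in seq_len(k - 1)) {
      for (y in (x + 1):k) {
        n_comp <- n_comp + 1
        if (al[x] != al[y]) n_diff <- n_diff + 1
      }
    }
  }
  list(pi = if (n_comp > 0) n_diff / n_comp else NA_real_,
       n_diff = n_diff, n_comp = n_comp)
}

dxy_oracle <- function(calledA, altA, calledB, altB) {
  n_diff <- 0
  n_comp <- 0
  for (i in seq_len(nrow(calledA))) {
    a <- site_alleles(calledA[i, ], altA[i, ])
    b <- site_alleles(calledB[i, ], altB[i, ])
    for (x in seq_along(a)) {
      for (y in seq_along(b)) {
        n_comp <- n_comp + 1
        if (a[x] != b[y]) n_diff <- n_diff + 1
      }
    }
  }
  list(dxy = if (n_comp > 0) n_diff / n_comp else NA_real_,
       n_diff = n_diff, n_comp = n_comp)
}

fst_oracle <- function(calledA, altA, calledB, altB) {
  wA <- pi_oracle(calledA, altA)
  wB <- pi_oracle(calledB, altB)
  btw <- dxy_oracle(calledA, altA, calledB, altB)
  within <- (wA$n_diff + wB$n_diff) / (wA$n_comp + wB$n_comp)
  between <- btw$n_diff / btw$n_comp
  1 - within / between
}

# --- naive EHH by direct substring comparison -------------------------------
ehh_oracle <- function(H, focal, core, x) {
  carriers <- which(H[, focal] == core)
  n <- length(carriers)
  rng <- if (x >= focal) focal:x else x:focal
  ident <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(H[carriers[i], rng] == H[carriers[j], rng])) ident <- ident + 1
    }
  }
  ident / choose(n, 2)
}

# --- exhaustive minimum spanning tree for small node sets -------------------
spanning_tree_weights <- function(d) {
  n <- nrow(d)
  pairs <- utils::combn(n, 2)
  n_e <- ncol(pairs)
  picks <- utils::combn(n_e, n - 1)
  weights <- c()
  for (k in seq_len(ncol(picks))) {
    sel <- picks[, k]
    # connectivity check by union of components
    comp <- seq_len(n)
    for (e in sel) {
      a <- comp[pairs[1, e]]
      b <- comp[pairs[2, e]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) {
      weights <- c(weights, sum(d[cbind(pairs[1, sel], pairs[2, sel])]))
    }
  }
  weights
}

# --- delete-one-block jackknife recomputation -------------------------------
jackknife_oracle <- function(abba_blocks, baba_blocks) {
  A <- sum(abba_blocks)
  B <- sum(baba_blocks)
  m <- length(abba_blocks)
  D <- (A - B) / (A + B)
  dj <- vapply(seq_len(m), function(j) {
    a <- A - abba_blocks[j]
    b <- B - baba_blocks[j]
    (a - b) / (a + b)
  }, numeric(1))
  se <- sqrt((m - 1) / m * sum((dj - mean(dj))^2))
  list(D = D, se = se, Z = D / se, p = 2 * pnorm(-abs(D / se)))
}

# --- toy VCF text fixtures ---------------------------------------------------
write_test_vcf <- function(path, records, samples,
                           contigs = c(chr1 = 100000L), phased_header = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# random genotype matrix with missing data, for property tests
random_gm <- function(n_sites, n_samples, miss_prob = 0.15, seed = 1,
                      invariant_prob = 0.2) {
  set.seed(seed)
  called <- matrix(ifelse(runif(n_sites * n_samples) < miss_prob, 0L, 2L),
                   n_sites, n_samples)
  invariant <- runif(n_sites) < invariant_prob
  alt <- matrix(0L, n_sites, n_samples)
  for (i in which(!invariant)) {
    for (j in seq_len(n_samples)) {
      if (called[i, j] == 2L) alt[i, j] <- sample(0:2, 1)
    }
  }
  # sites where no alt was drawn are effectively invariant records too
  samples <- paste0("S", seq_len(n_samples))
  colnames(called) <- colnames(alt) <- samples
  geno_matrix(
    contig = rep("chr1", n_sites), pos = seq_len(n_sites) * 10L,
    ref = rep("A", n_sites),
    alt = ifelse(invariant, NA_character_, "T"),
    called = called, alt_count = alt,
    is_variant = !invariant, samples = samples
  )
}
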