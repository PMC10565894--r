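#' Per-site derived-allele frequencies for a four-taxon test
#'
#' Computes alternate-allele frequencies for the (P1, P2, P3, outgroup) trio
#' and polarizes them against the outgroup: when the outgroup's alternate
#' frequency exceeds 0.5 the site is re-oriented (all four frequencies flipped
#' to `1 - p`), so the derived allele is the one rare or absent in the
#' outgroup. A polymorphic outgroup down-weights the site through the
#' `(1 - p4)` factor of the pattern weights rather than dropping it. Sites
#' where any of the four populations has zero called alleles are dropped.
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map tibble (`sample`, `population`).
#' @param p1,p2,p3,outgroup Population labels; must be four disjoint,
#'   non-empty populations.
#' @return A tibble with columns `contig`, `pos`, `p1`, `p2`, `p3`, `p4`
#'   (derived-allele frequencies) and `n1`--`n4` (called allele counts); the
#'   trio labels are stored as the `trio` attribute.
#' @export
derived_freqs <- function(gm, popmap, p1, p2, p3, outgroup) {
  pops <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(pops)) stop("P1, P2, P3 and outgroup must be disjoint")
  absent <- setdiff(pops, popmap$population)
  if (length(absent) > 0) {
    stop("population(s) absent from map: ", paste(absent, collapse = ", "))
  }
  ov <- overlapping_populations(popmap, pops)
  if (length(ov) > 0) {
    stop("sample(s) assigned to more than one test population: ",
         paste(ov, collapse = ", "))
  }

  use <- which(gm$is_variant)
  cnt <- pop_counts(gm_subset(gm, use), popmap, pops)
  called <- vapply(cnt, `[[`, numeric(length(use)), "called")
  alt <- vapply(cnt, `[[`, numeric(length(use)), "alt")
  if (length(use) == 1) {
    called <- matrix(called, nrow = 1)
    alt <- matrix(alt, nrow = 1)
  }
  ok <- rowSums(called == 0) == 0
  called <- called[ok, , drop = FALSE]
  alt <- alt[ok, , drop = FALSE]
  freq <- alt / called
  flip <- freq[, 4] > 0.5
  freq[flip, ] <- 1 - freq[flip, , drop = FALSE]

  out <- tibble::tibble(
    contig = gm$contig[use][ok], pos = gm$pos[use][ok],
    p1 = freq[, 1], p2 = freq[, 2], p3 = freq[, 3], p4 = freq[, 4],
    n1 = as.integer(called[, 1]), n2 = as.integer(called[, 2]),
    n3 = as.integer(called[, 3]), n4 = as.integer(called[, 4])
  )
  attr(out, "trio") <- c(P1 = p1, P2 = p2, P3 = p3, outgroup = outgroup)
  out
}

overlapping_populations <- function(popmap, pops) {
  sub <- popmap[popmap$population %in% pops, , drop = FALSE]
  unique(sub$sample[duplicated(sub$sample)])
}

# frequency-weighted pattern contributions
abba_weight <- function(p1, p2, p3, p4) (1 - p1) * p2 * p3 * (1 - p4)
baba_weight <- function(p1, p2, p3, p4) p1 * (1 - p2) * p3 * (1 - p4)

#' ABBA/BABA weighted sums with jackknife blocks
#'
#' Per site, `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)`.
#' Sites are partitioned into `m_blocks` contiguous blocks (genome order)
#' holding as-equal-as-possible numbers of informative sites
#' (`ABBA + BABA > 0`), the resampling unit of the block jackknife.
#'
#' @param freqs A frequency table from [derived_freqs()].
#' @param m_blocks Number of jackknife blocks (default 20).
#' @return An object of class `pattern_sums`: totals, number of informative
#'   sites, and a per-block tibble of partial sums.
#' @export
pattern_sums <- function(freqs, m_blocks = 20) {
  if (m_blocks < 2) stop("need at least 2 jackknife blocks")
  abba <- abba_weight(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
  baba <- baba_weight(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
  informative <- (abba + baba) > 0
  n_inf <- sum(informative)
  if (n_inf < m_blocks) {
    stop("only ", n_inf, " informative sites for ", m_blocks, " blocks")
  }
  # contiguous blocks balanced by informative-site count
  rank_inf <- cumsum(informative)
  grp <- pmin(ceiling(rank_inf * m_blocks / n_inf), m_blocks)
  grp[grp < 1L] <- 1L
  blocks <- tibble::tibble(
    block = seq_len(m_blocks),
    abba = as.numeric(rowsum(abba, grp, reorder = TRUE)),
    baba = as.numeric(rowsum(baba, grp, reorder = TRUE)),
    n_informative = as.integer(rowsum(as.integer(informative), grp))
  )
  structure(
    list(
      abba = sum(abba), baba = sum(baba),
      n_sites_used = n_inf, n_sites_total = length(abba),
      blocks = blocks, trio = attr(freqs, "trio")
    ),
    class = "pattern_sums"
  )
}

#' @export
print.pattern_sums <- function(x, ...) {
  cat(sprintf("<pattern_sums> ABBA = %.4f, BABA = %.4f over %d informative sites (%d blocks)\n",
              x$abba, x$baba, x$n_sites_used, nrow(x$blocks)))
  invisible(x)
}

#' Patterson's D statistic
#'
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)`; a significant excess
#' of either pattern gives a nonzero value, evidence of gene flow between P3
#' and one of P1/P2.
#'
#' @param sums A [pattern_sums()] object.
#' @return The D statistic, a number in `[-1, 1]`.
#' @export
patterson_d <- function(sums) {
  denom <- sums$abba + sums$baba
  if (denom <= 0) stop("no ABBA/BABA signal: zero pattern-sum denominator")
  (sums$abba - sums$baba) / denom
}

#' Block-jackknife test of Patterson's D
#'
#' Delete-one-block estimates `D_(-j)` give the jackknife standard error
#' `SE = sqrt(((m-1)/m) * sum_j (D_(-j) - mean)^2)`, from which `Z = D/SE`
#' and a two-sided normal p-value.
#'
#' @param sums A [pattern_sums()] object.
#' @return A one-row tibble (class `trio_result`) with the trio labels, `D`,
#'   `se`, `Z`, `p`, `n_blocks` and `n_sites`.
#' @export
jackknife_test <- function(sums) {
  bl <- sums$blocks
  m <- nrow(bl)
  D <- patterson_d(sums)
  d_minus <- (sums$abba - bl$abba - (sums$baba - bl$baba)) /
    (sums$abba - bl$abba + sums$baba - bl$baba)
  if (any(!is.finite(d_minus))) {
    stop("a jackknife block carries the entire ABBA/BABA signal")
  }
  se <- sqrt((m - 1) / m * sum((d_minus - mean(d_minus))^2))
  if (se == 0) {
    stop("degenerate jackknife variance: all leave-one-out estimates identical")
  }
  z <- D / se
  trio <- sums$trio
  if (is.null(trio)) trio <- c(P1 = NA, P2 = NA, P3 = NA, outgroup = NA)
  out <- tibble::tibble(
    P1 = trio[["P1"]], P2 = trio[["P2"]], P3 = trio[["P3"]],
    outgroup = trio[["outgroup"]],
    D = D, se = se, Z = z, p = 2 * stats::pnorm(-abs(z)),
    n_blocks = m, n_sites = sums$n_sites_used
  )
  class(out) <- c("trio_result", class(out))
  out
}

#' Patterson's D over all ingroup trios
#'
#' Enumerates every unordered trio of ingroup taxa against a fixed outgroup.
#' Within a trio the sister pair (P1, P2) is the arrangement maximizing the
#' BBAA weighted sum (the two taxa that share derived alleles most often,
#' the convention of trio-testing tools), and P1/P2 are then oriented so that
#' `D >= 0`. Significance is Bonferroni-corrected across trios.
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map.
#' @param ingroup Character vector of candidate ingroup taxa (>= 3 after
#'   exclusions).
#' @param outgroup Outgroup population label.
#' @param exclude Taxa to drop before enumerating trios.
#' @param m_blocks Jackknife blocks per trio.
#' @return A tibble with one [jackknife_test()] row per trio plus a `bbaa`
#'   column, sorted by `p`; attributes `n_trios` and `bonferroni_alpha`
#'   (`0.05 / n_trios`).
#' @export
all_trios <- function(gm, popmap, ingroup, outgroup, exclude = NULL,
                      m_blocks = 20) {
  taxa <- setdiff(ingroup, exclude)
  if (length(taxa) < 3) stop("need at least 3 ingroup taxa after exclusions")
  combos <- utils::combn(taxa, 3, simplify = FALSE)
  rows <- purrr::map_dfr(combos, function(tr) {
    # evaluate the three possible sister pairs
    arrangements <- list(
      c(tr[1], tr[2], tr[3]), c(tr[1], tr[3], tr[2]), c(tr[2], tr[3], tr[1])
    )
    scored <- purrr::map(arrangements, function(a) {
      fr <- derived_freqs(gm, popmap, a[1], a[2], a[3], outgroup)
      bbaa <- sum(fr$p1 * fr$p2 * (1 - fr$p3) * (1 - fr$p4))
      list(freqs = fr, bbaa = bbaa)
    })
    best <- scored[[which.max(vapply(scored, `[[`, numeric(1), "bbaa"))]]
    fr <- best$freqs
    sums <- pattern_sums(fr, m_blocks)
    if (patterson_d(sums) < 0) {
      lab <- attr(fr, "trio")
      fr2 <- fr
      fr2$p1 <- fr$p2
      fr2$p2 <- fr$p1
      fr2$n1 <- fr$n2
      fr2$n2 <- fr$n1
      attr(fr2, "trio") <- c(P1 = lab[["P2"]], P2 = lab[["P1"]],
                             P3 = lab[["P3"]], outgroup = lab[["outgroup"]])
      sums <- pattern_sums(fr2, m_blocks)
    }
    res <- jackknife_test(sums)
    res$bbaa <- best$bbaa
    res
  })
  rows <- dplyr::arrange(rows, .data$p)
  attr(rows, "n_trios") <- length(combos)
  attr(rows, "bonferroni_alpha") <- 0.05 / length(combos)
  rows
}
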