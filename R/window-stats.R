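#' Windowed admixture proportion f_d
#'
#' `f_d` divides the observed ABBA-BABA excess by its maximum attainable
#' value, obtained by substituting the donor population's frequency --
#' site by site, the larger of `p2` and `p3` (ties resolve to P3) -- into
#' both the P2 and P3 slots. `f_d` is reported missing whenever the window's
#' own D statistic is non-positive or the denominator vanishes: the statistic
#' is defined only for windows with an ABBA excess.
#'
#' @param freqs Frequency table from [derived_freqs()], restricted to one
#'   window.
#' @return A list with `fd`, `D`, `S` (numerator), `S_d` (denominator) and
#'   `n_sites` (informative sites).
#' @export
window_fd <- function(freqs) {
  if (nrow(freqs) == 0) stop("empty window: no sites with complete data")
  abba <- abba_weight(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
  baba <- baba_weight(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
  S <- sum(abba) - sum(baba)
  denom <- sum(abba) + sum(baba)
  D <- if (denom > 0) (sum(abba) - sum(baba)) / denom else NA_real_
  pd <- pmax(freqs$p2, freqs$p3)
  S_d <- sum(abba_weight(freqs$p1, pd, pd, freqs$p4)) -
    sum(baba_weight(freqs$p1, pd, pd, freqs$p4))
  fd <- if (!is.na(D) && D > 0 && S_d > 0) S / S_d else NA_real_
  list(fd = fd, D = D, S = S, S_d = S_d, n_sites = sum((abba + baba) > 0))
}

# shared pairwise-difference kernels (counts of differing / comparable pairs)
pi_parts <- function(called, alt) {
  list(diff = sum(alt * (called - alt)), comp = sum(called * (called - 1) / 2))
}
dxy_parts <- function(calledA, altA, calledB, altB) {
  list(
    diff = sum(altA * (calledB - altB) + (calledA - altA) * altB),
    comp = sum(calledA * calledB)
  )
}

#' Nucleotide diversity over a set of sites
#'
#' pixy-style estimator: per site with `k` called alleles of which `a` are
#' alternate, `a (k - a)` differing pairs out of `k (k - 1) / 2`; pi is the
#' ratio of sums. Invariant and monomorphic sites add only to the
#' denominator, so the estimate is per comparable site, robust to missing
#' data, and honest about invariant-site support.
#'
#' @param gm A [geno_matrix()] (typically already subset to a window).
#' @param popmap Population map.
#' @param pop Population label.
#' @return A list with `pi`, `n_diff`, `n_comp`; `pi` is `NA` when no
#'   comparable pairs exist.
#' @export
window_pi <- function(gm, popmap, pop) {
  cnt <- pop_counts(gm, popmap, pop)[[1]]
  parts <- pi_parts(cnt$called, cnt$alt)
  pi <- if (parts$comp > 0) parts$diff / parts$comp else NA_real_
  if (parts$comp == 0) message("pi undefined for '", pop, "': no comparable pairs")
  list(pi = pi, n_diff = parts$diff, n_comp = parts$comp)
}

#' Absolute divergence d_xy between two populations
#'
#' Average pairwise differences per comparable site for between-population
#' pairs, with invariant sites contributing to the denominator (pixy-style).
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map.
#' @param popA,popB Population labels.
#' @return A list with `dxy`, `n_diff`, `n_comp`.
#' @export
window_dxy <- function(gm, popmap, popA, popB) {
  cnt <- pop_counts(gm, popmap, c(popA, popB))
  parts <- dxy_parts(cnt[[1]]$called, cnt[[1]]$alt, cnt[[2]]$called, cnt[[2]]$alt)
  dxy <- if (parts$comp > 0) parts$diff / parts$comp else NA_real_
  if (parts$comp == 0) {
    message("d_xy undefined for '", popA, "' vs '", popB, "': no comparable pairs")
  }
  list(dxy = dxy, n_diff = parts$diff, n_comp = parts$comp)
}

#' Net divergence d_a
#'
#' `d_a = d_xy - (pi_A + pi_B) / 2` discounts divergence that predates the
#' species split by subtracting the average within-population diversity, a
#' proxy for (twice mutation rate times) divergence time.
#'
#' @param dxy,pi_A,pi_B Numbers (any `NA` propagates).
#' @return `d_a`, or `NA` if any input is missing.
#' @export
window_da <- function(dxy, pi_A, pi_B) {
  if (any(is.na(c(dxy, pi_A, pi_B)))) return(NA_real_)
  dxy - (pi_A + pi_B) / 2
}

#' Hudson-type F_ST over variant sites
#'
#' Ratio-of-sums estimator: one minus the ratio of the pooled
#' within-population pairwise difference rate to the between-population rate,
#' accumulated over variant sites only (per the windowed-scan convention for
#' this statistic).
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map.
#' @param popA,popB Population labels.
#' @return `F_ST`, or `NA` when between-population diversity is zero.
#' @export
window_fst <- function(gm, popmap, popA, popB) {
  v <- which(gm$is_variant)
  if (length(v) == 0) return(NA_real_)
  gmv <- gm_subset(gm, v)
  cnt <- pop_counts(gmv, popmap, c(popA, popB))
  wA <- pi_parts(cnt[[1]]$called, cnt[[1]]$alt)
  wB <- pi_parts(cnt[[2]]$called, cnt[[2]]$alt)
  btw <- dxy_parts(cnt[[1]]$called, cnt[[1]]$alt, cnt[[2]]$called, cnt[[2]]$alt)
  if (btw$comp == 0 || btw$diff == 0) return(NA_real_)
  within <- (wA$diff + wB$diff) / (wA$comp + wB$comp)
  between <- btw$diff / btw$comp
  1 - within / between
}

#' Per-window scan of introgression and divergence statistics
#'
#' Computes, for each window, any requested combination of the trio-based
#' `f_d` (with the window's own D), per-population pi, pairwise d_xy / d_a,
#' and Hudson F_ST. A site contributes to every window covering its position,
#' so overlapping (sliding) windows are supported. Windows with fewer than
#' `min_sites` usable variant sites are reported with missing statistics.
#'
#' @param gm A [geno_matrix()].
#' @param popmap Population map.
#' @param windows Window tibble from [make_windows()] (extra columns such as
#'   `rate` are carried through).
#' @param p1,p2,p3,outgroup Trio labels; give all four to obtain `fd` and
#'   window `D`.
#' @param pi_pops Populations for which to report pi.
#' @param dxy_pairs List of length-2 character vectors: pairs for d_xy and
#'   d_a (d_a also requires both pops in `pi_pops`; they are added
#'   automatically).
#' @param fst_pairs List of length-2 character vectors for F_ST.
#' @param min_sites Minimum usable variant sites per window; `NULL` picks
#'   100 for windows of 50 kb or more, 10 for 10 kb, and 1 below that,
#'   following common windowed-scan practice.
#' @return A tibble with one row per window: the window columns, `n_sites`
#'   (usable variant sites), `n_total` (all genotyped sites), then `D`, `fd`,
#'   `pi_<pop>`, `dxy_<A>_<B>`, `da_<A>_<B>`, `fst_<A>_<B>` as requested.
#'   Classed `intro_scan` for [ggplot2::autoplot()].
#' @export
scan_windows <- function(gm, popmap, windows, p1 = NULL, p2 = NULL, p3 = NULL,
                         outgroup = NULL, pi_pops = NULL, dxy_pairs = NULL,
                         fst_pairs = NULL, min_sites = NULL) {
  do_trio <- !is.null(p1) && !is.null(p2) && !is.null(p3) && !is.null(outgroup)
  if (is.null(min_sites)) {
    span <- stats::median(windows$end - windows$start)
    min_sites <- if (span >= 50000) 100 else if (span >= 10000) 10 else 1
  }
  dxy_pairs <- purrr::map(dxy_pairs, as.character)
  fst_pairs <- purrr::map(fst_pairs, as.character)
  pi_pops <- union(pi_pops, unlist(dxy_pairs))

  freqs <- NULL
  fidx <- NULL
  if (do_trio) {
    freqs <- derived_freqs(gm, popmap, p1, p2, p3, outgroup)
    gkey <- paste(gm$contig, gm$pos)
    fidx <- match(paste(freqs$contig, freqs$pos), gkey)  # sorted: freqs keep site order
  }
  idx <- window_site_index(gm, windows)

  rows <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    sites <- idx[[i]]
    sub <- gm_subset(gm, sites)
    out <- tibble::tibble(n_total = length(sites),
                          n_sites = sum(sub$is_variant))
    enough <- out$n_sites >= min_sites
    if (do_trio) {
      fi <- if (length(sites) > 0) {
        # sites is a contiguous run of gm indices; binary-search its span
        lo <- findInterval(sites[1] - 1L, fidx) + 1L
        hi <- findInterval(sites[length(sites)], fidx)
        if (lo > hi) freqs[0, , drop = FALSE] else freqs[lo:hi, , drop = FALSE]
      } else {
        freqs[0, , drop = FALSE]
      }
      if (enough && nrow(fi) > 0) {
        fd <- window_fd(fi)
        out$D <- fd$D
        out$fd <- fd$fd
      } else {
        out$D <- NA_real_
        out$fd <- NA_real_
      }
    }
    pis <- list()
    for (p in pi_pops) {
      pis[[p]] <- if (enough && length(sites) > 0) {
        suppressMessages(window_pi(sub, popmap, p)$pi)
      } else {
        NA_real_
      }
      out[[paste0("pi_", p)]] <- pis[[p]]
    }
    for (pr in dxy_pairs) {
      dxy <- if (enough && length(sites) > 0) {
        suppressMessages(window_dxy(sub, popmap, pr[1], pr[2])$dxy)
      } else {
        NA_real_
      }
      out[[paste0("dxy_", pr[1], "_", pr[2])]] <- dxy
      out[[paste0("da_", pr[1], "_", pr[2])]] <-
        window_da(dxy, pis[[pr[1]]], pis[[pr[2]]])
    }
    for (pr in fst_pairs) {
      out[[paste0("fst_", pr[1], "_", pr[2])]] <- if (enough && length(sites) > 0) {
        window_fst(sub, popmap, pr[1], pr[2])
      } else {
        NA_real_
      }
    }
    out
  })
  out <- dplyr::bind_cols(windows, rows)
  class(out) <- c("intro_scan", class(out))
  attr(out, "min_sites") <- min_sites
  out
}
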