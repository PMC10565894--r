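test_that("f_d hand-derived single-site cases", {
  mk <- function(p1, p2, p3, p4) {
    tibble::tibble(contig = "c", pos = 1L, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                   n1 = 4L, n2 = 4L, n3 = 4L, n4 = 4L)
  }
  # (0, 0.5, 1, 0): S = 0.5, donor = P3, S_D = 1 -> fd = 0.5
  r <- window_fd(mk(0, 0.5, 1, 0))
  expect_equal(r$fd, 0.5)
  expect_equal(r$S_d, 1)
  # fully donor-like P2 -> fd = 1
  expect_equal(window_fd(mk(0, 1, 1, 0))$fd, 1)
  # BABA excess -> D <= 0 -> fd missing
  r2 <- window_fd(mk(1, 0, 1, 0))
  expect_true(is.na(r2$fd))
  expect_true(r2$D <= 0)
  expect_error(window_fd(mk(numeric(0), numeric(0), numeric(0), numeric(0))),
               "empty")
})

test_that("f_d donor rule resolves ties to P3", {
  fr <- tibble::tibble(contig = "c", pos = 1L, p1 = 0, p2 = 0.6, p3 = 0.6,
                       p4 = 0, n1 = 4L, n2 = 4L, n3 = 4L, n4 = 4L)
  r <- window_fd(fr)
  # tie: pmax gives 0.6 either way, denominator uses 0.6 in both slots
  expect_equal(r$S_d, (1 - 0) * 0.6 * 0.6 * 1 - 0)
})

test_that("pi matches pair enumeration, invariant sites enter denominators only", {
  samples <- c("a1", "a2")
  pm <- population_map(samples, c("A", "A"))
  called <- matrix(2L, 2, 2, dimnames = list(NULL, samples))
  alt <- matrix(c(1L, 0L, 1L, 0L), 2, 2, dimnames = list(NULL, samples))
  gm <- geno_matrix(rep("c", 2), c(10L, 20L), c("A", "C"),
                    c("T", NA), called, alt, is_variant = c(TRUE, FALSE))
  # site 1: 4 called alleles, 2 alt -> 4 differing of 6 pairs
  r1 <- window_pi(gm_sub <- gm, pm, "A")
  expect_equal(r1$n_diff, 4)
  expect_equal(r1$n_comp, 12)       # 6 pairs at each of 2 sites
  expect_equal(r1$pi, 1 / 3)        # 4/12 once the invariant site is added
  oracle <- pi_oracle(called, alt)
  expect_equal(r1$pi, oracle$pi)

  # all sites invariant -> pi = 0
  gm_inv <- geno_matrix("c", 10L, "A", NA_character_,
                        matrix(2L, 1, 2, dimnames = list(NULL, samples)),
                        matrix(0L, 1, 2), is_variant = FALSE)
  expect_equal(window_pi(gm_inv, pm, "A")$pi, 0)
})

test_that("d_xy matches pair enumeration on the fixed-difference example", {
  samples <- c("a1", "b1")
  pm <- population_map(samples, c("A", "B"))
  called <- matrix(2L, 2, 2, dimnames = list(NULL, samples))
  alt <- matrix(c(0L, 0L, 2L, 0L), 2, 2, dimnames = list(NULL, samples))
  gm <- geno_matrix(rep("c", 2), c(10L, 20L), c("A", "C"), c("T", NA),
                    called, alt, is_variant = c(TRUE, FALSE))
  r <- window_dxy(gm, pm, "A", "B")
  expect_equal(r$dxy, 0.5)   # 4 differing of 8 cross pairs over 2 sites
  expect_equal(r$n_diff, 4)
  expect_equal(r$n_comp, 8)
  # identical monomorphic populations diverge by zero
  gm0 <- geno_matrix("c", 10L, "A", NA_character_, called[1, , drop = FALSE],
                     matrix(0L, 1, 2, dimnames = list(NULL, samples)),
                     is_variant = FALSE)
  expect_equal(window_dxy(gm0, pm, "A", "B")$dxy, 0)
})

test_that("pi, d_xy and F_ST equal brute-force enumeration on random data", {
  for (seed in 1:5) {
    gm <- random_gm(40, 6, miss_prob = 0.2, seed = seed)
    pm <- population_map(gm$samples, rep(c("A", "B"), each = 3))
    a_cols <- gm$samples[1:3]
    b_cols <- gm$samples[4:6]
    cA <- gm$called[, a_cols]; aA <- gm$alt_count[, a_cols]
    cB <- gm$called[, b_cols]; aB <- gm$alt_count[, b_cols]

    expect_equal(suppressMessages(window_pi(gm, pm, "A")$pi),
                 pi_oracle(cA, aA)$pi, tolerance = 1e-12)
    expect_equal(suppressMessages(window_dxy(gm, pm, "A", "B")$dxy),
                 dxy_oracle(cA, aA, cB, aB)$dxy, tolerance = 1e-12)

    v <- gm$is_variant
    fst <- window_fst(gm, pm, "A", "B")
    oracle <- fst_oracle(cA[v, , drop = FALSE], aA[v, , drop = FALSE],
                         cB[v, , drop = FALSE], aB[v, , drop = FALSE])
    if (!is.na(fst)) expect_equal(fst, oracle, tolerance = 1e-12)
  }
})

test_that("F_ST is 1 for a fixed difference and ~0 for identical frequencies", {
  samples <- paste0("s", 1:4)
  pm <- population_map(samples, c("A", "A", "B", "B"))
  called <- matrix(2L, 1, 4, dimnames = list(NULL, samples))
  alt_fixed <- matrix(c(0L, 0L, 2L, 2L), 1, 4, dimnames = list(NULL, samples))
  gm <- geno_matrix("c", 10L, "A", "T", called, alt_fixed)
  expect_equal(window_fst(gm, pm, "A", "B"), 1)

  # identical intermediate frequencies at large n: F_ST tends to 0
  big <- paste0("t", 1:100)
  pm_big <- population_map(big, rep(c("A", "B"), each = 50))
  called_big <- matrix(2L, 1, 100, dimnames = list(NULL, big))
  alt_big <- matrix(rep(c(0L, 2L), 50), 1, 100, dimnames = list(NULL, big))
  gm_big <- geno_matrix("c", 10L, "A", "T", called_big, alt_big)
  expect_lt(abs(window_fst(gm_big, pm_big, "A", "B")), 0.05)
})

test_that("d_a arithmetic and missing propagation", {
  expect_equal(window_da(0.5, 0, 0), 0.5)
  expect_equal(window_da(0.02, 0.01, 0.02), 0.005)
  expect_equal(window_da(0.3, 0.3, 0.3), 0)
  expect_true(is.na(window_da(NA, 0.1, 0.1)))
  expect_true(is.na(window_da(0.2, NA, 0.1)))
})

test_that("pixy property: invariant sites change denominators only", {
  for (seed in 6:8) {
    gm <- random_gm(30, 4, miss_prob = 0.1, seed = seed)
    pm <- population_map(gm$samples, rep(c("A", "B"), each = 2))
    gv <- gm_variant <- {
      idx <- which(gm$is_variant)
      geno_matrix(gm$contig[idx], gm$pos[idx], gm$ref[idx], gm$alt[idx],
                  gm$called[idx, , drop = FALSE],
                  gm$alt_count[idx, , drop = FALSE],
                  is_variant = gm$is_variant[idx], samples = gm$samples)
    }
    all_pi <- suppressMessages(window_pi(gm, pm, "A"))
    var_pi <- suppressMessages(window_pi(gv, pm, "A"))
    expect_equal(all_pi$n_diff, var_pi$n_diff)
    expect_gte(all_pi$n_comp, var_pi$n_comp)
    all_dxy <- suppressMessages(window_dxy(gm, pm, "A", "B"))
    var_dxy <- suppressMessages(window_dxy(gv, pm, "A", "B"))
    expect_equal(all_dxy$n_diff, var_dxy$n_diff)
    expect_gte(all_dxy$n_comp, var_dxy$n_comp)
  }
})

test_that("deleting genotypes never increases comparable pairs; complete-data pi is classical", {
  gm <- random_gm(25, 4, miss_prob = 0, seed = 11)
  pm <- population_map(gm$samples, rep("A", 4))
  full <- suppressMessages(window_pi(gm, pm, "A"))
  # knock out one genotype
  called <- gm$called; alt <- gm$alt_count
  called[3, 2] <- 0L; alt[3, 2] <- 0L
  gm2 <- geno_matrix(gm$contig, gm$pos, gm$ref, gm$alt, called, alt,
                     is_variant = gm$is_variant, samples = gm$samples)
  less <- suppressMessages(window_pi(gm2, pm, "A"))
  expect_lt(less$n_comp, full$n_comp)

  # classical average pairwise difference per site on complete data:
  # mean over sites of a(n-a)/C(n,2) = mean of 2 n p (1-p) / (n-1)
  n_al <- 8
  p <- rowSums(gm$alt_count) / n_al
  classical <- mean(2 * n_al * p * (1 - p) / (n_al - 1))
  expect_equal(full$pi, classical, tolerance = 1e-12)
})

test_that("scan_windows assigns sites to windows, handles overlap and min_sites", {
  sim <- simulate_msc(
    species_model("(((p1:8000,p2:8000):4000,p3:12000):8000,out:20000);",
                  Ne = 10000, samples = c(p1 = 2, p2 = 2, p3 = 2, out = 2),
                  theta = 2e-4,
                  pulses = data.frame(donor = "p3", recipient = "p2",
                                      time = 2000, prop = 0.3)),
    n_loci = 40, seed = 55
  )
  # all sites lie in the first 40 loci; a window beyond them is all-missing
  w <- tibble::tibble(contig = "sim_1", start = c(1L, 400001L),
                      end = c(400001L, 800001L))
  sc <- scan_windows(sim$gm, sim$popmap, w, p1 = "p1", p2 = "p2", p3 = "p3",
                     outgroup = "out", pi_pops = "p1", min_sites = 1)
  expect_equal(nrow(sc), 2L)
  expect_true(is.na(sc$fd[2]) && is.na(sc$pi_p1[2]))
  expect_equal(sc$n_total[2], 0L)

  # a site contributes to every overlapping window covering it
  w_ov <- tibble::tibble(contig = "sim_1", start = c(1L, 5001L),
                         end = c(10001L, 15001L))
  sc_ov <- scan_windows(sim$gm, sim$popmap, w_ov, pi_pops = "p1",
                        min_sites = 1)
  in_both <- sum(sim$gm$pos >= 5001 & sim$gm$pos < 10001)
  expect_equal(sum(sc_ov$n_total), length(sim$gm$pos[sim$gm$pos < 15001]) +
                 in_both)

  # min_sites blanks under-covered windows
  sc_strict <- scan_windows(sim$gm, sim$popmap, w, p1 = "p1", p2 = "p2",
                            p3 = "p3", outgroup = "out",
                            min_sites = 10000)
  expect_true(all(is.na(sc_strict$fd)))
})

test_that("scan_windows reproduces an independent per-window site loop", {
  sim <- simulate_msc(
    species_model("(((p1:8000,p2:8000):4000,p3:12000):8000,out:20000);",
                  Ne = 10000, samples = c(p1 = 2, p2 = 2, p3 = 2, out = 2),
                  theta = 2e-4,
                  pulses = data.frame(donor = "p3", recipient = "p2",
                                      time = 2000, prop = 0.3)),
    n_loci = 30, seed = 77
  )
  w <- sim$windows
  sc <- scan_windows(sim$gm, sim$popmap, w, p1 = "p1", p2 = "p2", p3 = "p3",
                     outgroup = "out", dxy_pairs = list(c("p1", "p2")),
                     min_sites = 1)
  fr <- derived_freqs(sim$gm, sim$popmap, "p1", "p2", "p3", "out")
  pm <- sim$popmap
  for (i in c(1, 7, 19)) {
    sel <- sim$gm$pos >= w$start[i] & sim$gm$pos < w$end[i]
    fsel <- fr$pos >= w$start[i] & fr$pos < w$end[i]
    # oracle fd via direct sums
    f <- fr[fsel, ]
    abba <- (1 - f$p1) * f$p2 * f$p3 * (1 - f$p4)
    baba <- f$p1 * (1 - f$p2) * f$p3 * (1 - f$p4)
    pd <- pmax(f$p2, f$p3)
    abba_d <- (1 - f$p1) * pd * pd * (1 - f$p4)
    baba_d <- f$p1 * (1 - pd) * pd * (1 - f$p4)
    D <- (sum(abba) - sum(baba)) / (sum(abba) + sum(baba))
    fd <- if (D > 0 && sum(abba_d - baba_d) > 0) {
      (sum(abba) - sum(baba)) / sum(abba_d - baba_d)
    } else {
      NA_real_
    }
    expect_equal(sc$fd[i], fd, tolerance = 1e-12)
    # oracle dxy by pair enumeration
    a_cols <- pm$sample[pm$population == "p1"]
    b_cols <- pm$sample[pm$population == "p2"]
    oracle <- dxy_oracle(sim$gm$called[sel, a_cols, drop = FALSE],
                         sim$gm$alt_count[sel, a_cols, drop = FALSE],
                         sim$gm$called[sel, b_cols, drop = FALSE],
                         sim$gm$alt_count[sel, b_cols, drop = FALSE])
    expect_equal(sc$dxy_p1_p2[i], oracle$dxy, tolerance = 1e-12)
  }
})
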