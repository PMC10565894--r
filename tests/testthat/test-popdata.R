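test_that("read_vcf applies the biallelic / complete-genotype filters", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_record("chr1", 100, "A", "T", c("0/0", "0/1", "1/1")),
    vcf_record("chr1", 200, "A", "T,G", c("0/0", "0/1", "0/2")),   # triallelic
    vcf_record("chr1", 300, "G", "C", c("0/0", "./.", "1/1"))      # missing
  ), samples = c("s1", "s2", "s3"))

  gm <- read_vcf(path, require_complete = TRUE)
  expect_equal(length(gm$pos), 1L)
  expect_equal(gm$pos, 100L)
  expect_equal(attr(gm, "n_records_read"), 3L)
  expect_equal(attr(gm, "n_records_kept"), 1L)

  gm2 <- read_vcf(path, require_complete = FALSE)
  expect_equal(gm2$pos, c(100L, 300L))
  expect_equal(unname(gm2$called[2, "s2"]), 0L)  # missing cell: zero called alleles
  expect_equal(unname(gm2$alt_count[2, "s2"]), 0L)
})

test_that("read_vcf keeps invariant sites only on request and flags them", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_record("chr1", 10, "A", ".", c("0/0", "0/0")),
    vcf_record("chr1", 20, "C", ".", c("0/0", "0/0")),
    vcf_record("chr1", 30, "G", "T", c("0/1", "0/0")),
    vcf_record("chr1", 40, "T", ".", c("0/0", "0/0")),
    vcf_record("chr1", 50, "A", "C", c("1/1", "0/0"))
  ), samples = c("s1", "s2"))

  gm <- read_vcf(path, keep_invariant = TRUE)
  expect_equal(length(gm$pos), 5L)
  expect_equal(sum(gm$is_variant), 2L)
  expect_true(all(gm$alt_count[!gm$is_variant, ] == 0L))

  gm_v <- read_vcf(path, keep_invariant = FALSE)
  expect_equal(gm_v$pos, c(30L, 50L))
})

test_that("read_vcf half-calls are fully missing and regions are validated", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_record("chr1", 100, "A", "T", c("0/.", "0/1")),
    vcf_record("chr1", 200, "A", "T", c("0/0", "1/1"))
  ), samples = c("s1", "s2"))
  gm <- read_vcf(path, require_complete = FALSE)
  expect_equal(unname(gm$called[1, "s1"]), 0L)  # "0/." treated as missing
  expect_equal(read_vcf(path, require_complete = TRUE)$pos, 200L)
  expect_error(read_vcf(path, region = "chr9:1-500"), "absent")
  expect_equal(read_vcf(path, region = "chr1:150-250",
                        require_complete = FALSE)$pos, 200L)
})

test_that("population map reading: order, headers, duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#sample\tpop", "s1\tred", "s2\tred", "s3\tyellow", "s4\tred"),
             path)
  pm <- read_population_map(path)
  expect_equal(nrow(pm), 4L)
  expect_equal(attr(pm, "populations"), c("red", "yellow"))

  writeLines(c("s1\tred", "s1\tyellow"), path)
  expect_error(read_population_map(path), "duplicate")
  writeLines(character(0), path)
  expect_error(read_population_map(path), "empty")
})

test_that("make_windows tiles exactly, truncates, and counts windows", {
  w <- make_windows(c(chr1 = 100000L), size = 50000, step = 50000)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(1L, 50001L))
  expect_equal(w$end, c(50001L, 100001L))

  # closed form: ceil((30000 - 10000) / 100) + 1 = 201 sliding windows
  w2 <- make_windows(c(chr1 = 30000L), size = 10000, step = 100)
  expect_equal(nrow(w2), 201L)

  w3 <- make_windows(c(chr1 = 5000L), size = 50000)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 5001L)

  expect_error(make_windows(c(chr1 = 1000L), size = 0), "positive")
  expect_error(make_windows(c(chr1 = 1000L), size = 10, step = 20), "step")
})

test_that("non-overlapping tilings cover every base exactly once", {
  for (L in c(49999L, 50000L, 50001L, 123457L)) {
    w <- make_windows(c(c1 = L), size = 50000, step = 50000)
    covered <- integer(L)
    for (i in seq_len(nrow(w))) {
      idx <- w$start[i]:(w$end[i] - 1L)
      covered[idx] <- covered[idx] + 1L
    }
    expect_true(all(covered == 1L), label = paste("coverage for L =", L))
  }
})

test_that("recombination rates transfer by the midpoint rule", {
  small <- tibble::tibble(contig = "chr1",
                          start = c(1L, 475001L, 975001L),
                          end = c(50001L, 525001L, 1025001L))
  big <- tibble::tibble(contig = "chr1", start = c(1L, 500001L),
                        end = c(500001L, 1000001L), rate = c(2.0, 7.5))
  out <- annotate_recombination(small, big)
  expect_equal(out$rate, c(2.0, 7.5, NA))  # straddler decided by its midpoint
  big_bad <- tibble::tibble(contig = "chr1", start = c(1L, 400001L),
                            end = c(500001L, 900001L), rate = c(1, 2))
  expect_error(annotate_recombination(small, big_bad), "overlapping")
})

test_that("window tables round-trip through the BED convention", {
  w <- make_windows(c(chr1 = 100000L), 50000)
  w$rate <- c(1.5, 3.25)
  path <- tempfile(fileext = ".tsv")
  write_window_table(w, path)
  expect_equal(as.data.frame(read_window_table(path)), as.data.frame(w))
})

test_that("extract_haplotypes demands phased complete biallelic genotypes", {
  path <- tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_record("chr1", 100, "A", "T", c("0|1", "1|1")),
    vcf_record("chr1", 200, "C", "G", c("0|0", "1|0")),
    vcf_record("chr1", 300, "G", "A", c("1|1", "0|1"))
  ), samples = c("s1", "s2"))
  panel <- extract_haplotypes(path, "chr1:1-1000", c("s1", "s2"))
  expect_equal(dim(panel), c(4L, 3L))
  expect_equal(panel$haplotypes[, 1], c(0L, 1L, 1L, 1L))

  # empty region still yields one (empty) row pair per sample
  empty <- extract_haplotypes(path, "chr1:900-999", c("s1", "s2"))
  expect_equal(dim(empty), c(4L, 0L))

  write_test_vcf(path, vcf_record("chr1", 100, "A", "T", c("0/1", "1|1")),
                 samples = c("s1", "s2"))
  expect_error(extract_haplotypes(path, "chr1:1-1000", c("s1", "s2")),
               "unphased")
  write_test_vcf(path, vcf_record("chr1", 100, "A", "T", c("0|1", ".|1")),
                 samples = c("s1", "s2"))
  expect_error(extract_haplotypes(path, "chr1:1-1000", c("s1", "s2")),
               "missing")
})

test_that("haplotype pairs collapse back to the diploid genotype matrix", {
  H <- matrix(c(0L, 1L, 1L, 1L,
                1L, 0L, 0L, 0L,
                0L, 0L, 1L, 0L), nrow = 4)
  panel <- hap_panel(H, positions = c(10L, 20L, 30L),
                     meta = tibble::tibble(
                       haplotype = c("x_1", "x_2", "y_1", "y_2"),
                       sample = c("x", "x", "y", "y")
                     ))
  gm <- collapse_haplotypes(panel, contig = "chr1")
  expect_equal(unname(gm$alt_count[, "x"]), c(1L, 1L, 0L))
  expect_equal(unname(gm$alt_count[, "y"]), c(2L, 0L, 1L))
  expect_true(all(gm$called == 2L))

  # full round trip: phased VCF -> extract_haplotypes -> collapse == read_vcf
  set.seed(77)
  Hr <- matrix(rbinom(6 * 8, 1, 0.4), nrow = 6)
  Hr[, 3] <- c(1L, 0L, 1L, 1L, 0L, 0L)  # guarantee a variant column
  pr <- hap_panel(Hr, positions = (1:8) * 50L,
                  meta = tibble::tibble(
                    haplotype = paste0(rep(c("a", "b", "c"), each = 2), "_", 1:2),
                    sample = rep(c("a", "b", "c"), each = 2)
                  ))
  gmr <- collapse_haplotypes(pr, contig = "chr1")
  path <- tempfile(fileext = ".vcf")
  write_vcf(gmr, path, panel = pr)
  back <- extract_haplotypes(path, "chr1:1-1000", c("a", "b", "c"))
  keep <- which(gmr$is_variant)  # invariant records are not biallelic SNPs
  expect_equal(back$haplotypes, Hr[, keep, drop = FALSE])
  expect_equal(unname(collapse_haplotypes(back)$alt_count),
               unname(read_vcf(path)$alt_count))
})

test_that("geno_matrix enforces its invariants", {
  expect_error(
    geno_matrix(c("c1", "c1"), c(10L, 10L), c("A", "A"), c("T", "T"),
                called = matrix(2L, 2, 1), alt_count = matrix(1L, 2, 1)),
    "strictly increasing"
  )
  expect_error(
    geno_matrix("c1", 10L, "A", "T",
                called = matrix(1L, 1, 1), alt_count = matrix(2L, 1, 1)),
    "exceeds"
  )
  expect_error(
    geno_matrix("c1", 10L, "A", NA_character_,
                called = matrix(2L, 1, 1), alt_count = matrix(1L, 1, 1),
                is_variant = FALSE),
    "invariant"
  )
})
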