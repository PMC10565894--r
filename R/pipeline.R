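#' Run the full introgression workflow from a config
#'
#' Orchestrates the stages in the order of a typical analysis: all-trio
#' D-statistics, the windowed f_d/F_ST/pi/d_xy scan for a focal trio, the
#' stratified epoch scan with correlations (and recombination bins when a
#' rate table is given), and optional EHH / haplotype-network stages for a
#' phased region. Each stage writes a tab-separated table with a commented
#' header carrying the manifest hash; a JSON manifest records the package
#' version, seed, parameter hash and per-stage row counts. Reruns with the
#' same config are bit-identical for the deterministic stages.
#'
#' @param config A named list or the path of a YAML file with entries:
#'   `vcf`, `popmap` (paths); `outgroup`; `p2`, `p3` and `p1` (a vector of P1
#'   taxa, first one used for the single-trio scan); optional `ingroup`
#'   (taxa for the all-trios stage; defaults to all non-outgroup
#'   populations), `exclude`, `window_size` (default 50000), `window_step`,
#'   `blocks` (default 20), `min_sites`, `rate_table` (BED-like TSV with
#'   rates), `keep_invariant` (default TRUE), `ehh` (list: `region`,
#'   `position`, `samples`), `hapnet` (list: `region`, `samples`), `seed`,
#'   `out_dir`.
#' @param stages Character subset of
#'   `c("dtrios", "windows", "epoch", "ehh", "hapnet")`.
#' @return The manifest, invisibly, with the result tables attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config,
                         stages = c("dtrios", "windows", "epoch", "ehh", "hapnet")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "introscan",
    version = as.character(utils::packageVersion("introscan")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    stages = list()
  )

  popmap <- read_population_map(cfg$popmap)
  gm <- read_vcf(cfg$vcf, keep_invariant = cfg$keep_invariant,
                 require_complete = cfg$require_complete)
  log_msg("read %d of %d VCF records (%d variant sites)",
          attr(gm, "n_records_kept"), attr(gm, "n_records_read"),
          sum(gm$is_variant))
  lens <- attr(gm, "contig_lengths")
  results <- list()

  if ("dtrios" %in% stages) {
    ingroup <- cfg$ingroup
    if (is.null(ingroup)) {
      ingroup <- setdiff(attr(popmap, "populations"), cfg$outgroup)
    }
    tr <- all_trios(gm, popmap, ingroup, cfg$outgroup,
                    exclude = cfg$exclude, m_blocks = cfg$blocks)
    write_stage_table(tr, file.path(cfg$out_dir, "dtrios.tsv"), manifest,
                      extra = sprintf("n_trios=%d\tbonferroni_alpha=%.6g",
                                      attr(tr, "n_trios"),
                                      attr(tr, "bonferroni_alpha")))
    manifest$stages$dtrios <- list(rows = nrow(tr),
                                   n_trios = attr(tr, "n_trios"),
                                   bonferroni_alpha = attr(tr, "bonferroni_alpha"))
    results$dtrios <- tr
  }

  if ("windows" %in% stages) {
    windows <- make_windows(lens, cfg$window_size, cfg$window_step)
    p1 <- cfg$p1[1]
    sc <- scan_windows(
      gm, popmap, windows, p1 = p1, p2 = cfg$p2, p3 = cfg$p3,
      outgroup = cfg$outgroup,
      pi_pops = c(p1, cfg$p2),
      dxy_pairs = list(c(p1, cfg$p2)),
      fst_pairs = list(c(cfg$p2, cfg$p3)),
      min_sites = cfg$min_sites
    )
    if (!is.null(cfg$rate_table)) {
      sc <- annotate_recombination(sc, read_window_table(cfg$rate_table))
    }
    write_stage_table(sc, file.path(cfg$out_dir, "windows.tsv"), manifest)
    manifest$stages$windows <- list(rows = nrow(sc),
                                    n_missing_fd = sum(is.na(sc$fd)))
    results$windows <- sc
  }

  if ("epoch" %in% stages && length(cfg$p1) >= 2) {
    windows <- make_windows(lens, cfg$window_size, cfg$window_step)
    es <- stratified_scan(gm, popmap, cfg$p1, cfg$p2, cfg$p3, cfg$outgroup,
                          windows, min_sites = cfg$min_sites)
    write_stage_table(es, file.path(cfg$out_dir, "epoch_scan.tsv"), manifest)
    manifest$stages$epoch <- list(rows = nrow(es))
    results$epoch <- es

    wl <- attr(es, "windows")
    if (!is.null(results$windows)) {
      sc <- results$windows
      fst_col <- grep("^fst_", names(sc), value = TRUE)[1]
      pi_col <- grep("^pi_", names(sc), value = TRUE)[1]
      corr <- dplyr::bind_rows(
        dplyr::mutate(correlate_windows(sc$fd, sc[[fst_col]]),
                      pair = paste0("fd_vs_", fst_col)),
        dplyr::mutate(correlate_windows(sc$fd, sc[[pi_col]]),
                      pair = paste0("fd_vs_", pi_col))
      )
      write_stage_table(corr, file.path(cfg$out_dir, "correlations.tsv"),
                        manifest)
      manifest$stages$correlations <- list(rows = nrow(corr))
      results$correlations <- corr
      if (!is.null(cfg$rate_table) && "rate" %in% names(sc)) {
        rb <- recombination_quantile_bins(sc)
        write_stage_table(rb, file.path(cfg$out_dir, "recomb_bins.tsv"),
                          manifest)
        manifest$stages$recomb_bins <- list(rows = nrow(rb))
        results$recomb_bins <- rb
      }
    }
  }

  if ("ehh" %in% stages && !is.null(cfg$ehh)) {
    panel <- extract_haplotypes(cfg$vcf, cfg$ehh$region, cfg$ehh$samples,
                                popmap)
    focal <- match(cfg$ehh$position, panel$positions)
    if (is.na(focal)) stop("EHH focal position absent from region")
    curve <- ehh_decay(panel, focal)
    write_stage_table(curve, file.path(cfg$out_dir, "ehh.tsv"), manifest)
    manifest$stages$ehh <- list(rows = nrow(curve))
    results$ehh <- curve
  }

  if ("hapnet" %in% stages && !is.null(cfg$hapnet)) {
    panel <- extract_haplotypes(cfg$vcf, cfg$hapnet$region,
                                cfg$hapnet$samples, popmap)
    net <- haplotype_network(unique_haplotypes(panel))
    write_stage_table(net$nodes, file.path(cfg$out_dir, "hapnet_nodes.tsv"),
                      manifest)
    write_stage_table(net$edges, file.path(cfg$out_dir, "hapnet_edges.tsv"),
                      manifest)
    manifest$stages$hapnet <- list(nodes = nrow(net$nodes),
                                   edges = nrow(net$edges))
    results$hapnet <- net
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

validate_config <- function(config) {
  required <- c("vcf", "popmap", "outgroup", "p1", "p2", "p3")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("config is missing: ", paste(missing, collapse = ", "))
  }
  roles <- c(config$p1, config$p2, config$p3, config$outgroup)
  if (anyDuplicated(roles)) {
    stop("overlapping population roles: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  }
  for (f in c(config$vcf, config$popmap, config$rate_table)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  defaults <- list(window_size = 50000, window_step = NULL, blocks = 20,
                   min_sites = NULL, keep_invariant = TRUE,
                   require_complete = TRUE, seed = 1L, out_dir = "introscan_out",
                   ingroup = NULL, exclude = NULL, rate_table = NULL,
                   ehh = NULL, hapnet = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$window_step)) config$window_step <- config$window_size
  config
}

write_stage_table <- function(x, path, manifest, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# introscan %s manifest_hash=%s",
                     manifest$version, manifest$config_hash), con)
  if (!is.null(extra)) writeLines(paste0("# ", extra), con)
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

log_msg <- function(fmt, ...) message(sprintf(paste0("[introscan] ", fmt), ...))
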