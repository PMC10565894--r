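#' Tile contigs with (possibly sliding) windows
#'
#' Windows are half-open `[start, end)` in 1-based coordinates, so a 50 kb
#' tiling of a 100 kb contig is exactly `[1, 50001)` and `[50001, 100001)`.
#' The last window is truncated at the contig end. For a contig of length
#' `L >= size` the window count is `ceil((L - size) / step) + 1`; shorter
#' contigs get a single truncated window.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param size Window size in bp.
#' @param step Step between window starts; `step = size` gives a
#'   non-overlapping tiling. Must satisfy `size >= step >= 1`.
#' @return A tibble with columns `contig`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size, step = size) {
  if (size < 1 || step < 1) stop("size and step must be positive")
  if (step > size) stop("step must not exceed size")
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  purrr::map_dfr(names(contig_lengths), function(ctg) {
    L <- contig_lengths[[ctg]]
    n <- if (L >= size) ceiling((L - size) / step) + 1 else 1
    start <- 1L + as.integer(step) * (seq_len(n) - 1L)
    tibble::tibble(
      contig = ctg, start = start,
      end = pmin(start + as.integer(size), as.integer(L) + 1L)
    )
  })
}

#' Transfer recombination rates from large to small windows
#'
#' Each small window inherits the rate (cM/Mb) of the unique large window
#' containing its midpoint; midpoints not covered by any large window get
#' `NA`.
#'
#' @param windows Small-window tibble (`contig`, `start`, `end`).
#' @param rate_windows Large-window tibble with an additional `rate` column;
#'   windows must not overlap within a contig.
#' @return `windows` with a `rate` column appended.
#' @export
annotate_recombination <- function(windows, rate_windows) {
  stopifnot(all(c("contig", "start", "end") %in% names(windows)),
            all(c("contig", "start", "end", "rate") %in% names(rate_windows)))
  out <- windows
  out$rate <- NA_real_
  for (ctg in unique(windows$contig)) {
    big <- rate_windows[rate_windows$contig == ctg, , drop = FALSE]
    if (nrow(big) == 0) next
    big <- big[order(big$start), , drop = FALSE]
    if (nrow(big) > 1 && any(big$start[-1] < big$end[-nrow(big)])) {
      stop("overlapping rate windows on contig ", ctg)
    }
    i <- windows$contig == ctg
    mid <- (windows$start[i] + windows$end[i]) / 2
    j <- findInterval(mid, big$start)
    hit <- j >= 1 & ifelse(j >= 1, mid < big$end[pmax(j, 1)], FALSE)
    out$rate[i][hit] <- big$rate[j[hit]]
  }
  out
}

#' Read a BED-like window/rate table
#'
#' Tab-separated `contig`, `start`, `end` (0-based half-open as in BED) with
#' an optional fourth `rate` column; lines starting with `#` are skipped.
#' Coordinates are converted to the package's internal 1-based half-open
#' convention.
#'
#' @param path Path to the table.
#' @return A window tibble.
#' @export
read_window_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  out <- tibble::tibble(
    contig = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]) + 1L
  )
  if (ncol(raw) >= 4) out$rate <- as.numeric(raw[[4]])
  out
}

#' Write a window table in BED convention
#'
#' @param windows Window tibble (1-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  bed <- windows
  bed$start <- bed$start - 1L
  bed$end <- bed$end - 1L
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# index range of sites falling in [start, end) per window; gm sites sorted
window_site_index <- function(gm, windows) {
  purrr::map(seq_len(nrow(windows)), function(i) {
    on <- which(gm$contig == windows$contig[i])
    if (length(on) == 0) return(integer(0))
    p <- gm$pos[on]
    lo <- findInterval(windows$start[i] - 1L, p) + 1L
    hi <- findInterval(windows$end[i] - 1L, p)
    if (lo > hi) integer(0) else on[lo:hi]
  })
}
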