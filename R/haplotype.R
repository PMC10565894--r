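#' Site-specific extended haplotype homozygosity
#'
#' Among the carriers of the core allele at the focal SNP, EHH at a site `x`
#' is the probability that two randomly drawn carrier haplotypes are
#' identical over the whole interval between the focus and `x`:
#' `EHH(x) = sum_k C(n_k, 2) / C(n_c, 2)` where the `n_k` are the sizes of
#' the identity classes of the carriers over that interval. The curve starts
#' at 1 at the focus and is non-increasing outward; extension stops on a side
#' once EHH drops below `cutoff` (use `cutoff = 0` for the full curve).
#' Slow decay relative to the alternative allele is the signature of a
#' recent selective sweep.
#'
#' @param panel A [hap_panel()] (complete, phased).
#' @param focal_index Column index of the focal SNP.
#' @param core_allele Core allele at the focus (0 or 1).
#' @param cutoff Truncation threshold (default 0.05).
#' @return An `ehh_curve` tibble: `position`, `distance` (bp from focus,
#'   signed), `ehh`; attributes `focal_pos`, `core_allele`, `n_core`.
#' @export
ehh <- function(panel, focal_index, core_allele, cutoff = 0.05) {
  H <- panel$haplotypes
  pos <- panel$positions
  if (focal_index < 1 || focal_index > ncol(H)) stop("focal_index out of range")
  focal <- H[, focal_index]
  if (length(unique(focal)) < 2) stop("focal site is monomorphic in the panel")
  carriers <- which(focal == core_allele)
  n_c <- length(carriers)
  if (n_c < 2) stop("fewer than 2 carriers of the core allele")
  denom <- choose(n_c, 2)

  side_curve <- function(direction) {
    cols <- if (direction > 0) {
      seq(focal_index + 1L, length.out = max(ncol(H) - focal_index, 0))
    } else {
      rev(seq_len(focal_index - 1L))
    }
    grp <- rep(1L, n_c)  # identity classes over [focus..x]
    out_pos <- integer(0)
    out_ehh <- numeric(0)
    for (x in cols) {
      key <- paste(grp, H[carriers, x])
      grp <- match(key, unique(key))
      e <- sum(choose(tabulate(grp), 2)) / denom
      out_pos <- c(out_pos, pos[x])
      out_ehh <- c(out_ehh, e)
      if (e < cutoff) break
    }
    tibble::tibble(position = out_pos, ehh = out_ehh)
  }

  left <- side_curve(-1)
  right <- side_curve(+1)
  curve <- dplyr::bind_rows(
    tibble::tibble(position = rev(left$position), ehh = rev(left$ehh)),
    tibble::tibble(position = pos[focal_index], ehh = 1),
    right
  )
  curve$distance <- curve$position - pos[focal_index]
  class(curve) <- c("ehh_curve", class(curve))
  attr(curve, "focal_pos") <- pos[focal_index]
  attr(curve, "core_allele") <- core_allele
  attr(curve, "n_core") <- n_c
  curve
}

#' EHH decay for both alleles at a focal SNP
#'
#' Convenience wrapper around [ehh()] returning both alleles' curves in one
#' tibble for plotting the swept-versus-background contrast.
#'
#' @inheritParams ehh
#' @return An `ehh_curve` tibble with an extra `allele` column.
#' @export
ehh_decay <- function(panel, focal_index, cutoff = 0.05) {
  out <- purrr::map_dfr(c(0L, 1L), function(a) {
    cv <- ehh(panel, focal_index, a, cutoff)
    cv$allele <- a
    cv
  })
  class(out) <- c("ehh_curve", class(out))
  attr(out, "focal_pos") <- panel$positions[focal_index]
  out
}

#' Collapse a haplotype panel to its unique haplotypes
#'
#' Identical rows are merged into nodes carrying an observed count and, when
#' the panel has population labels, a per-population composition.
#'
#' @param panel A [hap_panel()].
#' @return A `hap_nodes` tibble: `node`, `n`, `seq` (the 0/1 string), plus
#'   one `n_<population>` count column per population; the node-by-site
#'   matrix is kept in `attr(, "haplotypes")`.
#' @export
unique_haplotypes <- function(panel) {
  H <- panel$haplotypes
  if (nrow(H) == 0) stop("empty panel")
  key <- apply(H, 1, paste, collapse = "")
  first <- !duplicated(key)
  node_of <- match(key, key[first])
  nodes <- tibble::tibble(
    node = seq_len(sum(first)),
    n = as.integer(tabulate(node_of, sum(first))),
    seq = key[first]
  )
  if ("population" %in% names(panel$meta)) {
    pops <- unique(panel$meta$population)
    for (p in pops) {
      nodes[[paste0("n_", p)]] <- as.integer(
        tabulate(node_of[panel$meta$population == p], sum(first))
      )
    }
  }
  class(nodes) <- c("hap_nodes", class(nodes))
  attr(nodes, "haplotypes") <- H[first, , drop = FALSE]
  nodes
}

# deterministic Kruskal: edges sorted by (weight, node i, node j)
kruskal_mst <- function(d) {
  n <- nrow(d)
  if (n < 2) {
    return(tibble::tibble(from = integer(0), to = integer(0), steps = integer(0)))
  }
  pairs <- utils::combn(n, 2)
  e <- tibble::tibble(
    from = pairs[1, ], to = pairs[2, ],
    steps = d[cbind(pairs[1, ], pairs[2, ])]
  )
  e <- e[order(e$steps, e$from, e$to), , drop = FALSE]
  comp <- seq_len(n)
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- comp[e$from[i]]
    b <- comp[e$to[i]]
    if (a != b) {
      keep[i] <- TRUE
      comp[comp == b] <- a
    }
  }
  e[keep, , drop = FALSE]
}

# maximum edge weight on the MST path between each pair of nodes
mst_path_max <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$steps[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  pm <- matrix(0, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    queue <- list(c(s, 0))
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(NROW(adj[[cur[1]]]))) {
        if (NROW(adj[[cur[1]]]) == 0) break
        nb <- adj[[cur[1]]][k, ]
        if (!seen[nb[1]]) {
          seen[nb[1]] <- TRUE
          pm[s, nb[1]] <- max(cur[2], nb[2])
          queue <- c(queue, list(c(nb[1], pm[s, nb[1]])))
        }
      }
    }
  }
  pm
}

#' Infinite-sites haplotype network
#'
#' Builds a minimum spanning tree over the unique haplotypes under Hamming
#' (mutational-step) distances, with deterministic tie-breaking by
#' lexicographic node order. Non-tree pairs whose distance equals the maximum
#' edge weight on the tree path between them are flagged as alternative
#' edges -- the equally parsimonious "alternate connections" of classic
#' haplotype-network figures.
#'
#' @param nodes A `hap_nodes` tibble from [unique_haplotypes()].
#' @return A `hap_network` list with `nodes` and an `edges` tibble
#'   (`from`, `to`, `steps`, `in_tree`).
#' @export
haplotype_network <- function(nodes) {
  H <- attr(nodes, "haplotypes")
  if (is.null(H)) stop("nodes must come from unique_haplotypes()")
  n <- nrow(H)
  if (n == 1) {
    return(structure(
      list(nodes = nodes,
           edges = tibble::tibble(from = integer(0), to = integer(0),
                                  steps = integer(0), in_tree = logical(0))),
      class = "hap_network"
    ))
  }
  d <- hamming_matrix(H)
  tree <- kruskal_mst(d)
  tree$in_tree <- TRUE
  pm <- mst_path_max(n, tree)
  pairs <- utils::combn(n, 2)
  in_tree_key <- paste(tree$from, tree$to)
  alt <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (paste(a, b) %in% in_tree_key) return(NULL)
    if (d[a, b] == pm[a, b]) {
      tibble::tibble(from = a, to = b, steps = d[a, b], in_tree = FALSE)
    } else {
      NULL
    }
  })
  structure(list(nodes = nodes, edges = dplyr::bind_rows(tree, alt)),
            class = "hap_network")
}

hamming_matrix <- function(H) {
  n <- nrow(H)
  d <- matrix(0L, n, n)
  if (ncol(H) > 0) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(H[i, ] != H[j, ])
      }
    }
  }
  d
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("<hap_network> %d nodes, %d tree edges, %d alternative edges\n",
              nrow(x$nodes), sum(x$edges$in_tree), sum(!x$edges$in_tree)))
  invisible(x)
}
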