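#' Define a species model for coalescent simulation
#'
#' A rooted, ultrametric population tree (newick with branch lengths in
#' generations; tips contemporaneous), per-branch diploid effective sizes,
#' and zero or more unidirectional admixture pulses. Internal node labels in
#' the newick string can be used to address ancestral populations (e.g. to
#' pulse into the ancestor of two sisters).
#'
#' @param tree A newick string or `ape::phylo` with branch lengths in
#'   generations.
#' @param Ne A single diploid effective size for all branches, or a named
#'   vector keyed by tip/internal labels with an optional `.default` entry.
#' @param samples Named integer vector: diploid samples per tip population.
#' @param pulses Optional data frame with columns `donor`, `recipient`,
#'   `time` (generations before present) and `prop` (fraction of recipient
#'   lineages rerouted, in (0, 1)). Backward in time, each lineage present in
#'   the recipient at the pulse time moves to the donor with probability
#'   `prop`. Both populations must exist (not yet have merged root-ward) at
#'   that time.
#' @param theta Per-locus mutation rate: expected mutations per generation of
#'   total genealogy branch length; segregating sites per locus are
#'   `Poisson(theta * total branch length)` under infinite sites.
#' @param locus_bp Locus length in bp (sites are placed uniformly within).
#' @return An object of class `species_model`.
#' @export
species_model <- function(tree, Ne, samples, pulses = NULL,
                          theta = 2e-4, locus_bp = 10000L) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse newick tree")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2) stop("need at least two tip populations")

  depth <- ape::node.depth.edgelength(phy)  # distance from root
  total <- max(depth[seq_len(n_tip)])
  if (any(abs(depth[seq_len(n_tip)] - total) > 1e-6 * max(total, 1))) {
    stop("tree must be ultrametric (contemporaneous tips)")
  }
  node_time <- total - depth  # generations before present

  int_nodes <- (n_tip + 1):(n_tip + phy$Nnode)
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep(NA_character_, phy$Nnode)
              else ifelse(nzchar(phy$node.label), phy$node.label, NA_character_))
  auto <- paste0("anc_", seq_len(phy$Nnode))
  labels[int_nodes] <- ifelse(is.na(labels[int_nodes]), auto, labels[int_nodes])
  if (anyDuplicated(labels)) stop("duplicate population labels in tree")

  ne_of <- function(lab) {
    if (length(Ne) == 1 && is.null(names(Ne))) return(as.numeric(Ne))
    if (lab %in% names(Ne)) return(as.numeric(Ne[[lab]]))
    if (".default" %in% names(Ne)) return(as.numeric(Ne[[".default"]]))
    stop("no Ne for population '", lab, "'")
  }
  ne_vec <- vapply(labels, ne_of, numeric(1))
  if (any(ne_vec <= 0)) stop("Ne must be positive")

  # split events: children of each internal node merge into it
  splits <- purrr::map_dfr(int_nodes, function(v) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(ch) != 2) stop("tree must be strictly bifurcating")
    tibble::tibble(time = node_time[v], child1 = ch[1], child2 = ch[2], parent = v)
  })
  splits <- splits[order(splits$time), , drop = FALSE]

  # active interval of each population (for pulse validation)
  t_start <- node_time
  t_start[seq_len(n_tip)] <- 0
  parent_of <- integer(n_tip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  t_merge <- rep(Inf, length(labels))
  nonroot <- which(parent_of > 0)
  t_merge[nonroot] <- node_time[parent_of[nonroot]]

  if (!is.null(pulses)) {
    pulses <- tibble::as_tibble(pulses)
    stopifnot(all(c("donor", "recipient", "time", "prop") %in% names(pulses)))
    if (any(pulses$prop <= 0 | pulses$prop >= 1)) {
      stop("pulse proportions must lie in (0, 1)")
    }
    for (i in seq_len(nrow(pulses))) {
      for (role in c("donor", "recipient")) {
        lab <- pulses[[role]][i]
        v <- match(lab, labels)
        if (is.na(v)) stop("unknown pulse ", role, ": '", lab, "'")
        if (pulses$time[i] < t_start[v] || pulses$time[i] >= t_merge[v]) {
          stop("invalid pulse timing: '", lab, "' does not exist at generation ",
               pulses$time[i])
        }
      }
    }
  }

  unknown <- setdiff(names(samples), phy$tip.label)
  if (length(unknown) > 0) {
    stop("samples given for unknown population(s): ", paste(unknown, collapse = ", "))
  }
  s <- stats::setNames(rep(0L, n_tip), phy$tip.label)
  s[names(samples)] <- as.integer(samples)
  samples <- s
  if (!is.null(pulses)) {
    for (lab in unique(c(pulses$donor, pulses$recipient))) {
      v <- match(lab, labels)
      tips_below <- if (v <= n_tip) lab else {
        labels[intersect(seq_len(n_tip), node_descendants(phy, v))]
      }
      if (sum(samples[tips_below]) == 0) {
        stop("population '", lab, "' used by a pulse has zero samples")
      }
    }
  }
  if (sum(samples) < 2) stop("need at least two sampled diploids in total")

  structure(
    list(
      phy = phy, labels = labels, node_time = node_time, ne = ne_vec,
      splits = splits, pulses = pulses, samples = samples,
      theta = theta, locus_bp = as.integer(locus_bp), n_tip = n_tip
    ),
    class = "species_model"
  )
}

# tip indices below node v (simple edge walk; avoids extra deps)
node_descendants <- function(phy, v) {
  out <- v
  frontier <- v
  while (length(frontier) > 0) {
    ch <- phy$edge[phy$edge[, 1] %in% frontier, 2]
    out <- c(out, ch)
    frontier <- ch
  }
  unique(out)
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf(
    "<species_model> %d tip populations, %d sampled diploids, %d pulse(s), theta = %g\n",
    x$n_tip, sum(x$samples), if (is.null(x$pulses)) 0 else nrow(x$pulses), x$theta
  ))
  invisible(x)
}

# flatten model into the event arrays the C++ simulator consumes
model_events <- function(model) {
  ev <- tibble::tibble(
    time = model$splits$time, type = 0L,
    a = model$splits$child1 - 1L, b = model$splits$child2 - 1L,
    c = model$splits$parent - 1L, p = 0
  )
  if (!is.null(model$pulses)) {
    pv <- tibble::tibble(
      time = model$pulses$time, type = 1L,
      a = match(model$pulses$recipient, model$labels) - 1L,
      b = match(model$pulses$donor, model$labels) - 1L,
      c = -1L, p = model$pulses$prop
    )
    ev <- dplyr::bind_rows(ev, pv)
  }
  # pulses fire before a split at the same instant
  ev[order(ev$time, ev$type, method = "radix", decreasing = c(FALSE, TRUE)), ]
}

#' Simulate unlinked multispecies-coalescent loci
#'
#' Each locus draws one genealogy under the structured coalescent on the
#' species model (admixture pulses reroute lineages with probability `prop`
#' at the pulse time) and mutations under infinite sites. Loci are emitted as
#' unlinked blocks laid head-to-tail on one synthetic contig, with locus
#' boundaries available as windows. Identical seeds give identical output.
#'
#' @param model A [species_model()].
#' @param n_loci Number of independent loci.
#' @param seed Integer seed (required: every simulation is reproducible).
#' @return A list of class `msc_sim`: `gm` (a [geno_matrix()] of diploid
#'   genotypes; all sites variant), `popmap`, `windows` (one per locus),
#'   and `truth` (per-locus tibble with `n_sites`, `pulse_traced`, the
#'   lineage-level pulse bookkeeping `lineages_moved` / `lineages_present`,
#'   `total_length`, `tmrca`).
#' @export
simulate_msc <- function(model, n_loci, seed) {
  if (n_loci < 1) stop("n_loci must be at least 1")
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(as.integer(seed))

  pops_with <- names(model$samples)[model$samples > 0]
  lin_pop0 <- rep(match(pops_with, model$labels) - 1L,
                  times = 2L * model$samples[pops_with])
  n_lin <- length(lin_pop0)
  sample_names <- unlist(purrr::map(pops_with, function(p) {
    paste0(p, "_", seq_len(model$samples[[p]]))
  }))
  sample_pop <- rep(pops_with, times = model$samples[pops_with])

  ev <- model_events(model)
  lb <- model$locus_bp
  n_pulses <- if (is.null(model$pulses)) 0L else nrow(model$pulses)

  loci <- vector("list", n_loci)
  truth <- tibble::tibble(
    locus = seq_len(n_loci),
    start = (seq_len(n_loci) - 1L) * lb + 1L,
    end = seq_len(n_loci) * lb + 1L,
    n_sites = 0L, pulse_traced = FALSE,
    lineages_moved = 0L, lineages_present = 0L,
    total_length = NA_real_, tmrca = NA_real_
  )

  for (i in seq_len(n_loci)) {
    sim <- sim_locus_cpp(lin_pop0, model$ne, ev$time, ev$type, ev$a, ev$b,
                         ev$c, ev$p, model$theta)
    S <- nrow(sim$geno)
    if (S > lb) stop("more mutations than locus positions; lower theta or raise locus_bp")
    pos <- if (S > 0) sort(sample.int(lb, S)) else integer(0)
    # diploid alt counts: sum consecutive lineage pairs
    alt <- sim$geno[, seq(1, n_lin, by = 2), drop = FALSE] +
      sim$geno[, seq(2, n_lin, by = 2), drop = FALSE]
    loci[[i]] <- list(pos = pos + (i - 1L) * lb, alt = alt)
    truth$n_sites[i] <- S
    truth$pulse_traced[i] <- if (n_pulses > 0) any(sim$pulse_hit) else FALSE
    if (n_pulses > 0) {
      truth$lineages_moved[i] <- sum(sim$pulse_moved)
      truth$lineages_present[i] <- sum(sim$pulse_present)
    }
    truth$total_length[i] <- sim$total_length
    truth$tmrca[i] <- sim$tmrca
  }

  pos_all <- unlist(purrr::map(loci, "pos"))
  alt_all <- do.call(rbind, purrr::map(loci, "alt"))
  n_sites <- length(pos_all)
  gm <- geno_matrix(
    contig = rep("sim_1", n_sites), pos = pos_all,
    ref = rep("A", n_sites), alt = rep("T", n_sites),
    called = matrix(2L, n_sites, length(sample_names),
                    dimnames = list(NULL, sample_names)),
    alt_count = alt_all, is_variant = rep(TRUE, n_sites),
    samples = sample_names
  )
  attr(gm, "contig_lengths") <- c(sim_1 = n_loci * lb)

  structure(
    list(
      gm = gm,
      popmap = population_map(sample_names, sample_pop),
      windows = tibble::tibble(contig = "sim_1", start = truth$start,
                               end = truth$end),
      truth = truth, model = model, seed = as.integer(seed)
    ),
    class = "msc_sim"
  )
}

#' @export
print.msc_sim <- function(x, ...) {
  cat(sprintf("<msc_sim> %d loci, %d segregating sites, %d samples (seed %d)\n",
              nrow(x$truth), sum(x$truth$n_sites), length(x$gm$samples), x$seed))
  invisible(x)
}

# default ladder model used by the epoch designs: an ingroup of five
# populations at nested divergence depths (focal P2, its sister, then
# mid/deep splits and the donor) plus an outgroup.
default_epoch_tree <- function(t1 = 4000, t2 = 8000, t3 = 12000,
                               t4 = 20000, t5 = 40000) {
  sprintf(
    "(((((focal:%d,sister:%d)anc_sisters:%d,mid:%d):%d,deep:%d):%d,donor:%d):%d,outgroup:%d);",
    t1, t1, t2 - t1, t2, t3 - t2, t3, t4 - t3, t4, t5 - t4, t5
  )
}

#' Simulate the stratified-P1 epoch design
#'
#' Builds the package's reference ladder model -- five nested ingroup
#' populations (`focal` = P2, `sister`, `mid`, `deep`, plus the `donor` = P3)
#' and an `outgroup` -- and injects one admixture pulse from the donor either
#' into the terminal `focal` branch (`"recent"`: detectable with every P1) or
#' into the ancestor of (`focal`, `sister`) (`"ancestral"`: invisible with
#' `sister` as P1, detectable with deeper P1 taxa).
#'
#' @param pulse_epoch `"recent"` or `"ancestral"`.
#' @param f Pulse proportion in (0, 1), or 0 for the no-pulse null.
#' @param n_loci Number of loci.
#' @param seed Integer seed.
#' @param Ne Diploid effective size (default 10000).
#' @param samples_per_pop Diploids sampled per ingroup population (default 4;
#'   the outgroup gets 3).
#' @param theta,locus_bp Passed to [species_model()].
#' @return An `msc_sim` list (see [simulate_msc()]); the truth tibble gains
#'   the attribute `epoch`.
#' @export
simulate_epoch_panel <- function(pulse_epoch = c("recent", "ancestral"), f,
                                 n_loci, seed, Ne = 10000,
                                 samples_per_pop = 4, theta = 2e-4,
                                 locus_bp = 10000L) {
  pulse_epoch <- match.arg(pulse_epoch)
  recipient <- switch(pulse_epoch, recent = "focal", ancestral = "anc_sisters")
  pulse_time <- switch(pulse_epoch, recent = 400, ancestral = 6000)
  pulses <- if (f > 0) {
    tibble::tibble(donor = "donor", recipient = recipient,
                   time = pulse_time, prop = f)
  } else {
    NULL
  }
  samples <- c(focal = samples_per_pop, sister = samples_per_pop,
               mid = samples_per_pop, deep = samples_per_pop,
               donor = samples_per_pop, outgroup = 3L)
  model <- species_model(default_epoch_tree(), Ne = Ne, samples = samples,
                         pulses = pulses, theta = theta, locus_bp = locus_bp)
  sim <- simulate_msc(model, n_loci, seed)
  attr(sim$truth, "epoch") <- pulse_epoch
  sim
}

#' Simulate a planted-sweep haplotype panel
#'
#' Background haplotypes draw alleles independently per site (site frequencies
#' uniform on (0.05, 0.95)). Carriers of the derived focal allele copy one
#' core haplotype outward from the focus, switching permanently -- once per
#' side, with per-site probability `recomb_prob` -- onto an independent
#' background haplotype, emulating recombination off a swept core.
#'
#' @param n_hap Total haplotypes.
#' @param n_sites Number of sites (odd numbers center the focus exactly).
#' @param sweep_frequency Frequency of the swept focal allele, in (0, 1).
#' @param recomb_prob Per-site switch probability for carriers.
#' @param seed Integer seed.
#' @return A [hap_panel()]; `attr(, "focal_index")` marks the focal column,
#'   and carriers have allele 1 there.
#' @export
simulate_sweep_panel <- function(n_hap = 20, n_sites = 201,
                                 sweep_frequency = 0.5, recomb_prob = 0.02,
                                 seed) {
  if (sweep_frequency <= 0 || sweep_frequency >= 1) {
    stop("sweep_frequency must lie in (0, 1)")
  }
  set.seed(as.integer(seed))
  focal <- (n_sites + 1L) %/% 2L
  n_car <- max(2L, round(sweep_frequency * n_hap))
  if (n_car > n_hap - 2L) stop("sweep frequency leaves fewer than 2 background haplotypes")

  p_site <- stats::runif(n_sites, 0.05, 0.95)
  draw_bg <- function() as.integer(stats::runif(n_sites) < p_site)
  H <- t(vapply(seq_len(n_hap), function(i) draw_bg(), integer(n_sites)))
  core <- draw_bg()

  for (i in seq_len(n_car)) {
    hap <- core
    for (side in c(-1L, 1L)) {
      run <- which(stats::runif(n_sites) < recomb_prob)
      sw <- if (side < 0) focal - run else focal + run
      sw <- sw[sw >= 1 & sw <= n_sites]
      if (length(sw) > 0) {
        cut <- if (side < 0) max(sw) else min(sw)
        bg <- draw_bg()
        if (side < 0) hap[1:cut] <- bg[1:cut] else hap[cut:n_sites] <- bg[cut:n_sites]
      }
    }
    H[i, ] <- hap
  }
  H[, focal] <- c(rep(1L, n_car), rep(0L, n_hap - n_car))

  panel <- hap_panel(
    H, positions = seq_len(n_sites) * 100L,
    meta = tibble::tibble(
      haplotype = paste0("hap_", seq_len(n_hap)),
      sample = paste0("S", rep(seq_len(ceiling(n_hap / 2)), each = 2)[seq_len(n_hap)]),
      population = c(rep("swept", n_car), rep("background", n_hap - n_car))
    )
  )
  attr(panel, "focal_index") <- focal
  panel
}
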