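#' Simulation configuration for synthetic scRNA-seq data
#'
#' The generator emulates droplet scRNA-seq counts: negative-binomial genes
#' with log-normal per-cell library-size factors, grouped cells, and planted
#' mCCC events in which a sender group over-expresses a metabolite's
#' producing enzymes and a receiver group over-expresses the sensor by a
#' common fold change. Enzyme and filler genes share one baseline mean;
#' sensor genes get their own, lower, baseline (`sensor_base_mean`), because
#' transporters and receptors are lowly expressed in real data and the
#' regime in which sensor expression is limiting is the one a co-expression
#' score must operate in.
#'
#' @param n_groups number of cell groups (default 4).
#' @param cells_per_group cells per group (default 100).
#' @param n_genes total genes; knowledgebase genes come first, the remainder
#'   are uninformative fillers (default 60).
#' @param base_mean NB baseline mean for enzyme and filler genes (default 0.5).
#' @param sensor_base_mean NB baseline mean for sensor genes (default 0.05).
#' @param dispersion NB size parameter (default 2).
#' @param libsize_sdlog sd (log scale) of per-cell library factors
#'   (default 0.3).
#' @param fold_change default fold change of planted events (> 1).
#' @param planted_events `NULL` (no signal), or a data frame with columns
#'   `sender`, `metabolite_id`, `sensor_gene`, `receiver` and optionally
#'   `fold_change`.
#' @param decoys optional data frame (`group`, `metabolite_id`, `fold`) whose
#'   consuming enzymes are boosted - such a group must not be called a sender.
#' @param seed RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_groups = 4, cells_per_group = 100,
                              n_genes = 60, base_mean = 0.5,
                              sensor_base_mean = 0.05, dispersion = 2,
                              libsize_sdlog = 0.3, fold_change = 4,
                              planted_events = NULL, decoys = NULL,
                              seed = 1) {
  stopifnot(n_groups >= 1, cells_per_group >= 1, fold_change > 1)
  if (!is.null(planted_events)) {
    need <- c("sender", "metabolite_id", "sensor_gene", "receiver")
    stopifnot(all(need %in% names(planted_events)))
    if (is.null(planted_events$fold_change)) {
      planted_events$fold_change <- fold_change
    }
    stopifnot(all(planted_events$fold_change > 1))
  }
  structure(list(n_groups = n_groups, cells_per_group = cells_per_group,
                 n_genes = n_genes, base_mean = base_mean,
                 sensor_base_mean = sensor_base_mean,
                 dispersion = dispersion, libsize_sdlog = libsize_sdlog,
                 fold_change = fold_change, planted_events = planted_events,
                 decoys = decoys, seed = as.integer(seed)),
            class = "simulation_config")
}

.sim_group_names <- function(n) sprintf("G%d", seq_len(n))

#' Default planted scenario on the fixture knowledgebase
#'
#' Five planted events over four groups, fold change 4. The metabolites
#' (D-glucose, L-alanine, cholesterol) are chosen so that their enzyme and
#' sensor genes overlap no other fixture metabolite's - planting them
#' perturbs no other metabolite's aggregate - and so that their sensors all
#' require uptake (transporters and nuclear receptors). The second factor
#' matters for ground-truth bookkeeping: the co-expression statistic alone
#' cannot distinguish which receiver group a strongly producing sender
#' signals to, so receiver identity in this scenario is carried by the
#' influx gate, which is exactly the role the flux constraint plays on real
#' data. Metabolites planted between two sender groups share one receiver,
#' keeping the implied (sender, receiver) combinations inside the truth set.
#'
#' @param fold_change planted fold change (default 4).
#' @param cells_per_group cells per group (default 100).
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
default_scenario <- function(fold_change = 4, cells_per_group = 100,
                             seed = 1) {
  g <- .sim_group_names(4)
  ev <- data.frame(
    sender        = g[c(1, 4, 2, 1, 3)],
    metabolite_id = c("HMDB0000122", "HMDB0000122", "HMDB0000161",
                      "HMDB0000161", "HMDB0000067"),
    sensor_gene   = c("SLC2A1", "SLC2A1", "SLC7A8", "SLC7A8", "RORA"),
    receiver      = g[c(2, 2, 3, 3, 4)],
    stringsAsFactors = FALSE)
  simulation_config(n_groups = 4, cells_per_group = cells_per_group,
                    fold_change = fold_change, planted_events = ev,
                    seed = seed)
}

#' Many-event scenario for robustness analyses
#'
#' Twenty planted events across eight groups, built so the detectable event
#' set is discrete (every event strongly planted) rather than trailing a
#' continuum of borderline effects: only metabolites whose sensors all
#' require uptake are used (so the influx gate localizes receivers), every
#' sensor of a planted metabolite is planted, each metabolite signals to a
#' single receiver group, and no two metabolites share enzyme or sensor
#' genes. Several sender groups per metabolite and a fold-4 boost confined
#' to a minority of groups keep the permutation null well below the
#' observed scores.
#'
#' @param cells_per_group cells per group (default 120, so that a 50%
#'   down-sampled replicate retains enough cells per group for stable group
#'   means).
#' @param fold_change planted fold change (default 4).
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
robustness_scenario <- function(cells_per_group = 120, fold_change = 4,
                                seed = 1) {
  plant <- list(
    # metabolite, sensors, senders, receiver
    list("HMDB0000641", c("SLC1A5", "SLC38A2"), c("G2", "G5", "G6"), "G1"),
    list("HMDB0000122", "SLC2A1",               c("G3", "G6", "G7"), "G2"),
    list("HMDB0000161", "SLC7A8",               c("G4", "G7", "G8"), "G3"),
    list("HMDB0000067", c("RORA", "NR1H3"), c("G5", "G6", "G7", "G8"), "G4"))
  ev <- do.call(rbind, lapply(plant, function(p) {
    expand.grid(sender = p[[3]], metabolite_id = p[[1]],
                sensor_gene = p[[2]], receiver = p[[4]],
                stringsAsFactors = FALSE)
  }))
  simulation_config(n_groups = 8, cells_per_group = cells_per_group,
                    fold_change = fold_change, planted_events = ev,
                    seed = seed)
}

#' Scenario for spatial-colocalization evaluation
#'
#' Two gene-disjoint metabolites (D-glucose, L-alanine), each with a single
#' sender group signalling to every other group at graded fold changes
#' (8 down to 2). Together with fold-scaled mock spatial data
#' ([generate_mock_spatial()] with `scale_by_fold = TRUE`) this creates the
#' within-metabolite gradient the communication-colocalization correlation
#' measures: pairs receiving a stronger planted signal both score higher
#' and colocalize more strongly.
#'
#' @param cells_per_group cells per group (default 100).
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
spatial_scenario <- function(cells_per_group = 100, seed = 1) {
  g <- .sim_group_names(8)
  folds <- c(8, 6, 5, 4, 3, 2.5, 2)
  ev <- rbind(
    data.frame(sender = "G1", metabolite_id = "HMDB0000122",
               sensor_gene = "SLC2A1", receiver = g[2:8],
               fold_change = folds, stringsAsFactors = FALSE),
    data.frame(sender = "G2", metabolite_id = "HMDB0000161",
               sensor_gene = "SLC7A8", receiver = g[c(1, 3:8)],
               fold_change = folds, stringsAsFactors = FALSE))
  simulation_config(n_groups = 8, cells_per_group = cells_per_group,
                    planted_events = ev, seed = seed)
}

#' Generate a synthetic scRNA-seq dataset with planted mCCC truth
#'
#' @param cfg a [simulation_config()].
#' @param kb the knowledgebase supplying enzyme and sensor genes (default the
#'   bundled fixture); planted genes must exist in it.
#' @return list with `dataset` (raw-count [expression_dataset()]) and
#'   `truth` (a `synthetic_truth`: the planted event table plus the planted
#'   sender and receiver sets for flux construction).
#' @export
generate_synthetic_dataset <- function(cfg, kb = fixture_knowledgebase()) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(kb, "metacomm_kb"))
  sensor_genes <- unique(kb$sensors$sensor_gene)
  enzyme_genes <- setdiff(unique(kb$enzymes$gene), sensor_genes)
  kb_genes <- c(enzyme_genes, sensor_genes)
  n_fill <- max(0, cfg$n_genes - length(kb_genes))
  genes <- c(kb_genes, if (n_fill > 0) sprintf("FILLER%02d", seq_len(n_fill)))

  groups <- .sim_group_names(cfg$n_groups)
  n_cells <- cfg$n_groups * cfg$cells_per_group
  cell_groups <- rep(groups, each = cfg$cells_per_group)
  cells <- sprintf("cell%04d", seq_len(n_cells))

  base <- stats::setNames(rep(cfg$base_mean, length(genes)), genes)
  base[sensor_genes] <- cfg$sensor_base_mean

  # per (group, gene) fold multipliers
  fold <- matrix(1, nrow = cfg$n_groups, ncol = length(genes),
                 dimnames = list(groups, genes))
  ev <- cfg$planted_events
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      m <- ev$metabolite_id[i]
      prod <- kb$enzymes$gene[kb$enzymes$metabolite_id == m &
                                kb$enzymes$direction == "producing"]
      sgene <- ev$sensor_gene[i]
      if (length(prod) == 0 ||
          !all(c(prod, sgene) %in% genes) ||
          !any(kb$sensors$metabolite_id == m & kb$sensors$sensor_gene == sgene)) {
        stop(sprintf("planted event %d does not resolve in the knowledgebase", i),
             call. = FALSE)
      }
      if (!all(c(ev$sender[i], ev$receiver[i]) %in% groups)) {
        stop("planted event references an unknown group", call. = FALSE)
      }
      f <- ev$fold_change[i]
      fold[ev$sender[i], prod] <- pmax(fold[ev$sender[i], prod], f)
      fold[ev$receiver[i], sgene] <- max(fold[ev$receiver[i], sgene], f)
    }
  }
  if (!is.null(cfg$decoys)) {
    for (i in seq_len(nrow(cfg$decoys))) {
      m <- cfg$decoys$metabolite_id[i]
      cons <- kb$enzymes$gene[kb$enzymes$metabolite_id == m &
                                kb$enzymes$direction == "consuming"]
      cons <- intersect(cons, genes)
      g <- cfg$decoys$group[i]
      fold[g, cons] <- pmax(fold[g, cons], cfg$decoys$fold[i])
    }
  }

  set.seed(cfg$seed)
  lib <- exp(stats::rnorm(n_cells, mean = -cfg$libsize_sdlog^2 / 2,
                          sd = cfg$libsize_sdlog))
  mu <- (lib %o% base) * fold[cell_groups, , drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), size = cfg$dispersion,
                                  mu = as.vector(mu)),
                   nrow = n_cells, ncol = length(genes),
                   dimnames = list(cells, genes))

  ds <- expression_dataset(counts, stats::setNames(cell_groups, cells),
                           genes = genes, cells = cells, normalized = FALSE)

  truth_ev <- if (is.null(ev)) {
    data.frame(sender = character(), metabolite_id = character(),
               sensor_gene = character(), receiver = character(),
               fold_change = numeric(), stringsAsFactors = FALSE)
  } else ev
  sc <- kb$sensors$sensor_class[match(paste(truth_ev$metabolite_id,
                                            truth_ev$sensor_gene),
                                      paste(kb$sensors$metabolite_id,
                                            kb$sensors$sensor_gene))]
  truth_ev$sensor_class <- sc
  truth <- structure(list(
    events = truth_ev,
    senders = unique(truth_ev[, c("sender", "metabolite_id")]),
    receivers = unique(truth_ev[, c("receiver", "metabolite_id")]),
    groups = groups,
    metabolites = kb$metabolites$metabolite_id[kb$metabolites$active]),
    class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' Event keys of the planted truth
#'
#' @param truth a `synthetic_truth`.
#' @return character keys `sender|metabolite|sensor|receiver`, comparable
#'   with the keys used by [recapture_ratios()].
#' @export
truth_keys <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ev <- truth$events
  paste(ev$sender, ev$metabolite_id, ev$sensor_gene, ev$receiver, sep = "|")
}

#' Generate efflux and influx matrices consistent with a planted truth
#'
#' Planted sender entries receive efflux scores above the default pooled
#' percentile threshold (level plus small uniform noise); all other entries
#' are zero, i.e. at - and under the strict comparison, effectively below -
#' the threshold. Receiver influx is built the same way. A constant
#' non-planted level is the only construction compatible with "non-planted
#' entries fall below a pooled 25th-percentile threshold": any spread in the
#' majority class necessarily puts most of it above its own lower quartile.
#' Optional decoy events are forced to zero efflux so the flux gate removes
#' them.
#'
#' @param truth a `synthetic_truth`.
#' @param planted_level flux value given to planted entries (default 2, plus
#'   uniform noise on (0, 0.5)).
#' @param decoy_events optional data frame (`sender`, `metabolite_id`) whose
#'   efflux entries are set to 0 (below any pooled percentile threshold).
#' @param seed RNG seed.
#' @return list with components `efflux` and `influx` (both `flux_matrix`).
#' @export
generate_synthetic_flux <- function(truth, planted_level = 2,
                                    decoy_events = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  groups <- truth$groups
  mets <- truth$metabolites
  set.seed(seed)
  zero <- function() matrix(0, nrow = length(groups), ncol = length(mets),
                            dimnames = list(groups, mets))
  e <- zero()
  i <- zero()
  if (nrow(truth$senders) > 0) {
    idx <- cbind(truth$senders$sender, truth$senders$metabolite_id)
    e[idx] <- planted_level + stats::runif(nrow(idx), 0, 0.5)
  }
  if (nrow(truth$receivers) > 0) {
    idx <- cbind(truth$receivers$receiver, truth$receivers$metabolite_id)
    i[idx] <- planted_level + stats::runif(nrow(idx), 0, 0.5)
  }
  if (!is.null(decoy_events)) {
    e[cbind(decoy_events$sender, decoy_events$metabolite_id)] <- 0
  }
  list(efflux = flux_matrix(e, "efflux"), influx = flux_matrix(i, "influx"))
}

#' Generate mock spatial spot proportions that colocalize planted pairs
#'
#' Each cell type gets an independent gamma-distributed intensity per spot;
#' for every planted (sender, receiver) pair a shared per-spot factor is
#' mixed into both types' intensities with weight `colocalization_strength`,
#' then rows are normalized to proportions summing to 1. Strength 0 gives
#' independent (null) proportions; strength near 1 makes planted pairs
#' nearly rank-identical.
#'
#' @param truth a `synthetic_truth`.
#' @param n_spots number of spots (>= 10, default 100).
#' @param colocalization_strength mixing weight in `[0, 1]`.
#' @param scale_by_fold scale each pair's mixing weight by its planted fold
#'   change relative to the largest planted fold, so that more strongly
#'   communicating pairs colocalize more strongly (default `FALSE`: one
#'   common strength).
#' @param seed RNG seed.
#' @return spots x cell-types matrix of proportions (rows sum to 1).
#' @export
generate_mock_spatial <- function(truth, n_spots = 100,
                                  colocalization_strength = 0.9,
                                  scale_by_fold = FALSE, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), n_spots >= 10,
            colocalization_strength >= 0, colocalization_strength <= 1)
  groups <- truth$groups
  set.seed(seed)
  raw <- matrix(stats::rgamma(n_spots * length(groups), shape = 2, rate = 2),
                nrow = n_spots, dimnames = list(sprintf("spot%03d",
                                                        seq_len(n_spots)),
                                                groups))
  s <- colocalization_strength
  ev <- truth$events[truth$events$sender != truth$events$receiver, ,
                     drop = FALSE]
  if (nrow(ev) > 0) {
    fold <- if (scale_by_fold && !is.null(ev$fold_change)) {
      ev$fold_change / max(ev$fold_change)
    } else rep(1, nrow(ev))
    key <- paste(ev$sender, ev$receiver)
    pairs <- data.frame(sender = ev$sender, receiver = ev$receiver,
                        w = fold, stringsAsFactors = FALSE)
    pairs <- do.call(rbind, lapply(split(pairs, key), function(d) {
      d[which.max(d$w), , drop = FALSE]
    }))
  } else {
    pairs <- data.frame(sender = character(), receiver = character(),
                        w = numeric())
  }
  # each planted pair contributes one shared factor; a group in several
  # pairs averages its (weighted) factors, so every planted pair stays
  # positively correlated rather than the last factor overwriting earlier
  # ones
  fac_sum <- matrix(0, nrow = n_spots, ncol = length(groups),
                    dimnames = list(NULL, groups))
  fac_w <- stats::setNames(rep(0, length(groups)), groups)
  for (i in seq_len(nrow(pairs))) {
    f <- stats::rgamma(n_spots, shape = 2, rate = 2)
    w <- pairs$w[i]
    for (g in c(pairs$sender[i], pairs$receiver[i])) {
      fac_sum[, g] <- fac_sum[, g] + w * f
      fac_w[g] <- fac_w[g] + w
    }
  }
  shared <- fac_w > 0
  raw[, shared] <- (1 - s) * raw[, shared] +
    s * sweep(fac_sum[, shared, drop = FALSE], 2, fac_w[shared], "/")
  raw / rowSums(raw)
}
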