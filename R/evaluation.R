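#' Cell-type colocalization from spot deconvolution
#'
#' Spearman correlation (average-rank ties) of every pair of cell types'
#' deconvolved proportions across spatial spots. Constant proportion vectors
#' have no defined rank correlation and yield `NA`.
#'
#' @param props spots x cell-types matrix of proportions (rows from a
#'   deconvolution tool sum to ~1).
#' @return a symmetric cell-type x cell-type matrix with unit diagonal.
#' @export
colocalization_scores <- function(props) {
  props <- as.matrix(props)
  if (nrow(props) < 3) stop("need at least 3 spots", call. = FALSE)
  suppressWarnings(rho <- stats::cor(props, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' @rdname colocalization_scores
#' @param path TSV with spots as rows (first column spot id) and cell types
#'   as column headers.
#' @export
read_spot_proportions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                              check.names = FALSE))
}

#' Correlation between communication and spatial colocalization
#'
#' For every metabolite mediating detected events between at least
#' `min_pairs` distinct (sender, receiver) cell-type pairs, the Spearman
#' correlation across those pairs between the communication scores (summed
#' over sensors of the same metabolite and pair) and the pairs'
#' colocalization scores. Autocrine pairs are excluded (self-colocalization
#' is trivially 1).
#'
#' @param table a `comm_table`; only detected events
#'   ([significant_events()]) enter.
#' @param coloc symmetric colocalization matrix from
#'   [colocalization_scores()].
#' @param min_pairs minimum distinct cell-type pairs per metabolite
#'   (default 10).
#' @param significant_only restrict to detected events (default `TRUE`).
#' @return data frame with `metabolite_id`, `n_pairs`, `rho`, plus the median
#'   rho in `attr(, "median_rho")`; empty (with a warning) if no metabolite
#'   qualifies.
#' @export
comm_coloc_correlation <- function(table, coloc, min_pairs = 10,
                                   significant_only = TRUE) {
  stopifnot(inherits(table, "comm_table"))
  ev <- if (significant_only) significant_events(table) else table
  ev <- ev[ev$sender != ev$receiver, , drop = FALSE]
  missing_types <- setdiff(unique(c(ev$sender, ev$receiver)),
                           rownames(coloc))
  if (length(missing_types) > 0) {
    stop("cell type(s) absent from colocalization matrix: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(metabolite_id = character(), n_pairs = integer(),
                    rho = numeric(), stringsAsFactors = FALSE)
  for (m in unique(ev$metabolite_id)) {
    sub <- ev[ev$metabolite_id == m, , drop = FALSE]
    agg <- stats::aggregate(comm_score ~ sender + receiver, data = sub, FUN = sum)
    if (nrow(agg) < min_pairs) next
    cl <- coloc[cbind(agg$sender, agg$receiver)]
    rho <- suppressWarnings(stats::cor(agg$comm_score, cl,
                                       method = "spearman"))
    out <- rbind(out, data.frame(metabolite_id = m, n_pairs = nrow(agg),
                                 rho = rho, stringsAsFactors = FALSE))
  }
  if (nrow(out) == 0) {
    warning("no metabolite mediates events between >= min_pairs cell-type pairs",
            call. = FALSE)
  }
  attr(out, "median_rho") <- if (nrow(out) > 0) stats::median(out$rho) else NA_real_
  out
}

# Canonical event identity used by all set comparisons.
.event_keys <- function(table) {
  paste(table$sender, table$metabolite_id, table$sensor_gene, table$receiver,
        sep = "|")
}

#' Recapture ratios between two detected-event sets
#'
#' Events are identified by (sender, metabolite, sensor, receiver).
#' `over_total` divides the intersection by the perturbed (e.g. down-sampled)
#' set's size; `over_original` divides it by the original set's size.
#'
#' @param detected_subsample,detected_original character vectors of event
#'   keys, or `comm_table`s (their detected events are keyed automatically).
#' @return named numeric `c(over_total =, over_original =)`, `NA` for an
#'   empty denominator.
#' @export
recapture_ratios <- function(detected_subsample, detected_original) {
  as_keys <- function(x) {
    if (inherits(x, "comm_table")) .event_keys(significant_events(x))
    else as.character(x)
  }
  a <- unique(as_keys(detected_subsample))
  b <- unique(as_keys(detected_original))
  inter <- length(intersect(a, b))
  c(over_total = if (length(a) > 0) inter / length(a) else NA_real_,
    over_original = if (length(b) > 0) inter / length(b) else NA_real_)
}

#' Down-sample cells uniformly at random
#'
#' @param ds an [expression_dataset()].
#' @param fraction fraction of cells to retain, in (0, 1].
#' @param seed RNG seed (deterministic subset).
#' @return the subset dataset with group labels carried over.
#' @export
downsample_cells <- function(ds, fraction, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"),
            fraction > 0, fraction <= 1)
  n <- length(ds$cells)
  k <- max(1L, round(fraction * n))
  if (k == n) return(ds)
  set.seed(seed)
  keep <- sort(sample.int(n, k))
  expression_dataset(ds$x[keep, , drop = FALSE],
                     droplevels(ds$groups[keep]),
                     genes = ds$genes, cells = ds$cells[keep],
                     normalized = ds$normalized)
}

#' Inject uniform random read noise into raw counts
#'
#' Adds `ceiling(noise_to_signal * total_reads)` reads, each placed uniformly
#' at random on a (cell, gene) slot, emulating sequencing noise at a given
#' noise-to-signal ratio. The original reads are conserved exactly:
#' the noisy total equals the original total plus the added total.
#'
#' @param ds an [expression_dataset()] holding raw counts.
#' @param noise_to_signal ratio of added to original reads (>= 0).
#' @param seed RNG seed.
#' @return the noisy dataset (dense matrix), still raw counts.
#' @export
inject_noise <- function(ds, noise_to_signal, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"), noise_to_signal >= 0)
  if (ds$normalized) {
    stop("noise injection is defined on raw read counts", call. = FALSE)
  }
  if (noise_to_signal == 0) return(ds)
  x <- as.matrix(ds$x)
  total <- sum(x)
  n_add <- ceiling(noise_to_signal * total)
  set.seed(seed)
  slots <- sample.int(length(x), n_add, replace = TRUE)
  add <- tabulate(slots, nbins = length(x))
  x <- x + add
  expression_dataset(x, ds$groups, genes = ds$genes, cells = ds$cells,
                     normalized = FALSE)
}

#' Index of dispersion of an event's scores across conditions
#'
#' Variance-to-mean ratio using the population variance (denominator n);
#' undefined (`NA`) when the mean is zero.
#'
#' @param scores numeric vector of communication scores across >= 2
#'   conditions, or a matrix (events x conditions, row-wise IODs).
#' @return IOD value(s).
#' @export
index_of_dispersion <- function(scores) {
  iod1 <- function(v) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    mean((v - m)^2) / m
  }
  if (is.matrix(scores)) {
    if (ncol(scores) < 2) stop("need >= 2 conditions", call. = FALSE)
    apply(scores, 1, iod1)
  } else {
    if (length(scores) < 2) stop("need >= 2 conditions", call. = FALSE)
    iod1(scores)
  }
}

#' Assemble condition scores from several communication tables
#'
#' Unions the detected events of all tables (identity = sender, metabolite,
#' sensor, receiver) and builds the events x conditions matrix of
#' communication scores, scoring an event 0 in conditions where it was not
#' detected (absence is informative).
#'
#' @param tables list of `comm_table`s, one per condition.
#' @param labels condition labels (same length as `tables`).
#' @param significant_only use detected events only (default `TRUE`).
#' @return events x conditions numeric matrix with event keys as row names,
#'   class `condition_scores`.
#' @export
condition_scores <- function(tables, labels = names(tables),
                             significant_only = TRUE) {
  if (length(tables) < 2) stop("need >= 2 condition tables", call. = FALSE)
  if (is.null(labels) || length(labels) != length(tables)) {
    stop("labels must match the number of tables", call. = FALSE)
  }
  per <- lapply(tables, function(t) {
    ev <- if (significant_only) significant_events(t) else t
    stats::setNames(ev$comm_score, .event_keys(ev))
  })
  keys <- unique(unlist(lapply(per, names)))
  if (length(keys) == 0) stop("no detected event in any condition", call. = FALSE)
  cs <- vapply(per, function(v) {
    out <- v[keys]
    out[is.na(out)] <- 0
    unname(out)
  }, numeric(length(keys)))
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = length(keys))
  dimnames(cs) <- list(keys, labels)
  class(cs) <- c("condition_scores", class(cs))
  cs
}

#' Select the most condition-variable events by index of dispersion
#'
#' Ranks events by IOD (descending) and returns the top fraction; ties at
#' the boundary are all included. Events with zero IOD (no variation at all)
#' or undefined IOD (all-zero scores) are never selected. The achieved IOD
#' cutoff is reported so it can be quoted alongside the selection (it is
#' dataset-specific).
#'
#' @param cs a `condition_scores` matrix.
#' @param top_fraction fraction of rankable events to select (default 0.05).
#' @return data frame `event`, `iod`, sorted by IOD descending, with
#'   `attr(, "iod_cutoff")`.
#' @export
select_variable_events <- function(cs, top_fraction = 0.05) {
  iod <- index_of_dispersion(unclass(cs))
  iod <- iod[!is.na(iod)]   # events with a computable IOD form the ranking
  n <- length(iod)
  if (n == 0 || all(iod == 0)) {
    out <- data.frame(event = character(), iod = numeric())
    attr(out, "iod_cutoff") <- NA_real_
    return(out)
  }
  k <- ceiling(top_fraction * n)
  srt <- sort(iod, decreasing = TRUE)
  cutoff <- unname(srt[k])
  sel <- iod[iod >= cutoff & iod > 0]
  sel <- sort(sel, decreasing = TRUE)
  out <- data.frame(event = names(sel), iod = unname(sel),
                    stringsAsFactors = FALSE)
  attr(out, "iod_cutoff") <- cutoff
  out
}

#' Cluster condition profiles of events by k-means
#'
#' Z-scores each event's communication scores across conditions (mean 0,
#' sd 1; constant rows are excluded) and clusters the profiles with k-means
#' (Euclidean distance, 10 restarts). Deterministic given `seed`.
#'
#' @param cs a `condition_scores` matrix (or any events x conditions matrix).
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @return list: `clusters` (named integer vector), `centers` (k x
#'   conditions cluster mean profiles), `zscores` (the z-scored matrix),
#'   `excluded` (names of constant rows).
#' @export
cluster_events <- function(cs, k = 5, seed = 1) {
  m <- unclass(as.matrix(cs))
  sds <- apply(m, 1, stats::sd)
  excluded <- rownames(m)[sds == 0 | is.na(sds)]
  z <- m[sds > 0 & !is.na(sds), , drop = FALSE]
  z <- t(scale(t(z)))  # per-event z-score across conditions
  if (nrow(z) < k) {
    stop(sprintf("k = %d exceeds the %d clusterable events", k, nrow(z)),
         call. = FALSE)
  }
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10)
  list(clusters = km$cluster, centers = km$centers, zscores = z,
       excluded = excluded)
}

#' Per cell-type-pair network summary
#'
#' For every directed (sender, receiver) pair: the number of events and the
#' overall communication strength, the sum of -log10(FDR) over its events.
#'
#' @param table a `comm_table` (typically its detected events).
#' @param significant_only summarize detected events only (default `TRUE`).
#' @return data frame `sender`, `receiver`, `n_events`, `strength`.
#' @export
summarize_network <- function(table, significant_only = TRUE) {
  stopifnot(inherits(table, "comm_table"))
  ev <- if (significant_only) significant_events(table) else table
  if (nrow(ev) == 0) {
    return(data.frame(sender = character(), receiver = character(),
                      n_events = integer(), strength = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(ev$fdr <= 0 | ev$fdr > 1)) {
    stop("FDR values must be in (0, 1]", call. = FALSE)
  }
  df <- data.frame(sender = ev$sender, receiver = ev$receiver,
                   n_events = 1L, strength = -log10(ev$fdr),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_events, strength) ~ sender + receiver,
                          data = df, FUN = sum)
  agg$n_events <- as.integer(agg$n_events)
  rownames(agg) <- NULL
  agg[order(-agg$strength), ]
}
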