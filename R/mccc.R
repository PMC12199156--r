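#' Inference parameters for mCCC detection
#'
#' @param n_perm number of cell-label permutations for the null (default 1000).
#' @param seed RNG seed; the whole inference is deterministic given it.
#' @param fdr_cutoff Benjamini-Hochberg FDR threshold defining a detected
#'   event (default 0.05).
#' @param clamp_negative clamp negative enzyme aggregates to zero before the
#'   product (a net-consuming group is not a producer); default `TRUE`.
#' @param background_floor lower bound on the null mean used to normalize the
#'   communication score; events hitting it are flagged `background_floor`.
#' @param min_cells groups with fewer cells are excluded with a warning.
#' @param min_frac_expressing optional expression-fraction filter: an event is
#'   only scored if at least this fraction of sender cells express a producing
#'   enzyme of the metabolite and of receiver cells express the sensor.
#'   Default 0 (off).
#' @return a list of class `inference_params`.
#' @export
inference_params <- function(n_perm = 1000, seed = 1, fdr_cutoff = 0.05,
                             clamp_negative = TRUE, background_floor = 1e-8,
                             min_cells = 3, min_frac_expressing = 0) {
  stopifnot(n_perm >= 1, fdr_cutoff > 0, fdr_cutoff <= 1,
            background_floor > 0, min_cells >= 1,
            min_frac_expressing >= 0, min_frac_expressing <= 1)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fdr_cutoff = fdr_cutoff, clamp_negative = clamp_negative,
                 background_floor = background_floor,
                 min_cells = as.integer(min_cells),
                 min_frac_expressing = min_frac_expressing),
            class = "inference_params")
}

#' Aggregate enzyme expression per metabolite
#'
#' For each cell group and metabolite, the mean expression of the
#' metabolite's producing enzymes minus the mean expression of its consuming
#' enzymes (zero when it has none). This is a qualitative availability signal
#' for the metabolite in the sender group, not a quantitative abundance
#' estimate: a group whose consuming enzymes dominate gets a negative
#' aggregate and, under the default clamp, cannot act as a sender.
#'
#' @param profile a `group_profile` from [group_mean_expression()].
#' @param kb a `metacomm_kb`; only enzymes among the profile's genes count.
#' @return a groups x metabolites matrix; metabolites with no matched
#'   producing enzyme are absent.
#' @export
aggregate_enzyme_score <- function(profile, kb) {
  stopifnot(inherits(profile, "group_profile"), inherits(kb, "metacomm_kb"))
  genes <- colnames(profile$mean_expr)
  enz <- kb$enzymes[kb$enzymes$gene %in% genes, , drop = FALSE]
  prod <- enz[enz$direction == "producing", , drop = FALSE]
  mets <- unique(prod$metabolite_id)
  if (length(mets) == 0) {
    return(matrix(numeric(0), nrow = nrow(profile$mean_expr), ncol = 0,
                  dimnames = list(profile$groups, character())))
  }
  W <- .aggregation_weights(enz, genes, mets)
  A <- profile$mean_expr %*% W
  dimnames(A) <- list(profile$groups, mets)
  A
}

# genes x metabolites weight matrix: +1/n_producing on producing enzymes,
# -1/n_consuming on consuming enzymes, so M %*% W is the aggregate.
.aggregation_weights <- function(enz, genes, mets) {
  W <- matrix(0, nrow = length(genes), ncol = length(mets),
              dimnames = list(genes, mets))
  for (m in mets) {
    p <- enz$gene[enz$metabolite_id == m & enz$direction == "producing"]
    cns <- enz$gene[enz$metabolite_id == m & enz$direction == "consuming"]
    W[p, m] <- W[p, m] + 1 / length(p)
    if (length(cns) > 0) W[cns, m] <- W[cns, m] - 1 / length(cns)
  }
  W
}

#' Enzyme-sensor co-expression score
#'
#' The product of the sender group's aggregated enzyme expression and the
#' receiver group's mean sensor expression. With `clamp_negative` (default),
#' negative aggregates contribute zero, so net-consuming senders score 0.
#'
#' @param sender_aggregate aggregated enzyme score(s) of the sender group.
#' @param receiver_sensor_mean mean sensor expression in the receiver group
#'   (non-negative).
#' @param clamp_negative clamp negative aggregates to zero first.
#' @return the co-expression score S (vectorized).
#' @export
coexpression_score <- function(sender_aggregate, receiver_sensor_mean,
                               clamp_negative = TRUE) {
  if (any(receiver_sensor_mean < 0)) {
    stop("receiver sensor mean must be non-negative", call. = FALSE)
  }
  a <- if (clamp_negative) pmax(sender_aggregate, 0) else sender_aggregate
  a * receiver_sensor_mean
}

# Build the scoring context shared by the observed pass and every
# permutation: the dense submatrix of knowledgebase genes, the aggregation
# weights, the candidate (metabolite, sensor) pairs and the expanded event
# index (every sender x receiver group pair, autocrine included).
.mccc_context <- function(ds, kb, params) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(kb, "metacomm_kb"))
  ds <- .enforce_min_cells(ds, params$min_cells)

  enz <- kb$enzymes[kb$enzymes$gene %in% ds$genes, , drop = FALSE]
  sen <- kb$sensors[kb$sensors$sensor_gene %in% ds$genes, , drop = FALSE]
  prod_mets <- unique(enz$metabolite_id[enz$direction == "producing"])
  sen <- sen[sen$metabolite_id %in% prod_mets, , drop = FALSE]
  if (nrow(sen) == 0) {
    stop("no scorable metabolite-sensor pair after matching the knowledgebase",
         call. = FALSE)
  }
  mets <- unique(sen$metabolite_id)
  enz <- enz[enz$metabolite_id %in% mets, , drop = FALSE]

  rel_genes <- unique(c(enz$gene, sen$sensor_gene))
  X <- as.matrix(ds$x[, rel_genes, drop = FALSE])
  labels <- ds$groups
  glev <- levels(labels)
  sizes <- table(labels)[glev]

  W <- .aggregation_weights(enz, rel_genes, mets)
  pairs <- data.frame(metabolite_id = sen$metabolite_id,
                      sensor_gene = sen$sensor_gene,
                      sensor_class = sen$sensor_class,
                      met_idx = match(sen$metabolite_id, mets),
                      sensor_col = match(sen$sensor_gene, rel_genes),
                      stringsAsFactors = FALSE)

  G <- length(glev)
  ev <- expand.grid(sender = seq_len(G), receiver = seq_len(G),
                    pair = seq_len(nrow(pairs)))
  list(ds = ds, X = X, labels = labels, glev = glev,
       sizes = as.vector(sizes), W = W, mets = mets, pairs = pairs,
       events = ev,
       idx_agg = cbind(ev$sender, pairs$met_idx[ev$pair]),
       idx_sen = cbind(ev$receiver, pairs$sensor_col[ev$pair]))
}

# Group-mean matrix for an arbitrary label assignment (same sizes).
.group_means <- function(X, labels, glev) {
  M <- rowsum(X, labels)
  M[glev, , drop = FALSE] / as.vector(table(labels)[glev])
}

# Score every event given a group-mean matrix.
.score_events <- function(ctx, M, clamp_negative) {
  A <- M %*% ctx$W
  Ac <- if (clamp_negative) pmax(A, 0) else A
  Ac[ctx$idx_agg] * M[ctx$idx_sen]
}

#' Permutation null distribution of co-expression scores
#'
#' Shuffles the labels of all cells jointly (group sizes preserved),
#' recomputes the group means, and rebuilds the full co-expression score for
#' every (sender, metabolite, sensor, receiver) combination in each
#' permutation, so both score factors are drawn from the same shuffled
#' labeling. Deterministic given `seed`.
#'
#' @param ds a normalized [expression_dataset()].
#' @param kb a `metacomm_kb` matched to the dataset's genes.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param clamp_negative,min_cells see [inference_params()].
#' @return a list: `events` (one row per combination, with labels),
#'   `observed` (score under the true labels), `null` (events x `n_perm`
#'   matrix of permuted scores).
#' @export
permutation_null <- function(ds, kb, n_perm = 1000, seed = 1,
                             clamp_negative = TRUE, min_cells = 3) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  params <- inference_params(n_perm = n_perm, seed = seed,
                             clamp_negative = clamp_negative,
                             min_cells = min_cells)
  ctx <- .mccc_context(ds, kb, params)
  .permutation_null_ctx(ctx, params)
}

.permutation_null_ctx <- function(ctx, params) {
  M0 <- .group_means(ctx$X, ctx$labels, ctx$glev)
  observed <- .score_events(ctx, M0, params$clamp_negative)

  set.seed(params$seed)
  n_cells <- nrow(ctx$X)
  null <- matrix(NA_real_, nrow = nrow(ctx$events), ncol = params$n_perm)
  for (i in seq_len(params$n_perm)) {
    perm <- ctx$labels[sample.int(n_cells)]
    names(perm) <- NULL
    Mi <- .group_means(ctx$X, perm, ctx$glev)
    null[, i] <- .score_events(ctx, Mi, params$clamp_negative)
  }

  events <- data.frame(
    sender = ctx$glev[ctx$events$sender],
    metabolite_id = ctx$pairs$metabolite_id[ctx$events$pair],
    sensor_gene = ctx$pairs$sensor_gene[ctx$events$pair],
    sensor_class = ctx$pairs$sensor_class[ctx$events$pair],
    receiver = ctx$glev[ctx$events$receiver],
    stringsAsFactors = FALSE)
  list(events = events, observed = observed, null = null,
       group_means = M0, ctx = ctx)
}

#' One-tailed permutation p-value
#'
#' Add-one convention: `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p
#' is never 0 and ties with the observed score count as exceedances
#' (conservative).
#'
#' @param observed observed score (scalar, or vector paired with rows of a
#'   null matrix).
#' @param null_sample numeric vector of null scores, or a matrix with one row
#'   per observed value.
#' @return p-value(s) in `[1/(n_perm+1), 1]`.
#' @export
permutation_pvalue <- function(observed, null_sample) {
  if (is.matrix(null_sample)) {
    stopifnot(length(observed) == nrow(null_sample))
    n <- ncol(null_sample)
    cnt <- rowSums(null_sample >= observed)
  } else {
    n <- length(null_sample)
    if (n == 0) stop("null sample is empty", call. = FALSE)
    cnt <- vapply(observed, function(o) sum(null_sample >= o), numeric(1))
  }
  (1 + cnt) / (1 + n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up q-values in the input order; validates that all p-values
#' lie in (0, 1], which permutation p-values under the add-one convention
#' always do.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Background-normalized communication score
#'
#' The observed co-expression score divided by the mean of its permutation
#' null, bounded below by `floor` to avoid division by (near-)zero
#' backgrounds; events hitting the floor should carry the `background_floor`
#' flag.
#'
#' @param observed observed co-expression score(s), non-negative.
#' @param null_mean mean null score(s) for the same event.
#' @param floor small positive constant (default `1e-8`).
#' @return communication score(s) C.
#' @export
communication_score <- function(observed, null_mean, floor = 1e-8) {
  if (any(observed < 0)) stop("observed score must be >= 0", call. = FALSE)
  observed / pmax(null_mean, floor)
}

#' Infer metabolite-mediated cell-cell communication events
#'
#' Runs the full inference over every ordered pair of cell groups (autocrine
#' pairs included) and every metabolite-sensor pair scorable after matching
#' the knowledgebase to the dataset: enzyme aggregation, co-expression
#' scoring, joint label-permutation null, one-tailed p-values, BH FDR over
#' all scored events, and background-normalized communication scores.
#'
#' @param ds a normalized [expression_dataset()] (or pass
#'   `assume_normalized = TRUE` for externally normalized values).
#' @param kb a `metacomm_kb`, ideally pre-restricted with
#'   [match_genes_to_dataset()].
#' @param params an [inference_params()] object.
#' @param assume_normalized treat `ds` as normalized even if not flagged.
#' @return a `comm_table`: data frame with one row per event with positive
#'   co-expression score, columns `sender`, `metabolite_id`,
#'   `metabolite_name`, `sensor_gene`, `sensor_class`, `receiver`,
#'   `raw_aggregate`, `sensor_mean`, `coexpr_score`, `null_mean`,
#'   `comm_score`, `p_value`, `fdr`, `flags`; inference parameters in
#'   `attr(, "params")`.
#' @export
infer_mccc <- function(ds, kb, params = inference_params(),
                       assume_normalized = FALSE) {
  stopifnot(inherits(params, "inference_params"))
  if (!ds$normalized && !assume_normalized) {
    stop("dataset is not normalized; run normalize_expression() or set assume_normalized = TRUE",
         call. = FALSE)
  }
  ctx <- .mccc_context(ds, kb, params)
  pn <- .permutation_null_ctx(ctx, params)

  M0 <- pn$group_means
  A_raw <- M0 %*% ctx$W
  raw_aggregate <- A_raw[ctx$idx_agg]
  sensor_mean <- M0[ctx$idx_sen]

  tab <- pn$events
  tab$raw_aggregate <- raw_aggregate
  tab$sensor_mean <- sensor_mean
  tab$coexpr_score <- pn$observed
  tab$null_mean <- rowMeans(pn$null)
  tab$p_value <- permutation_pvalue(pn$observed, pn$null)

  keep <- tab$coexpr_score > 0
  if (params$min_frac_expressing > 0) {
    keep <- keep & .expression_fraction_ok(ctx, params$min_frac_expressing)
  }
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) {
    warning("no event with positive co-expression score", call. = FALSE)
  }

  tab$fdr <- bh_fdr(tab$p_value)
  floored <- tab$null_mean <= params$background_floor
  tab$comm_score <- communication_score(tab$coexpr_score, tab$null_mean,
                                        params$background_floor)
  tab$flags <- ifelse(floored, "background_floor", "")

  name_of <- kb$metabolites$name[match(tab$metabolite_id,
                                       kb$metabolites$metabolite_id)]
  tab$metabolite_name <- name_of
  tab <- tab[, c("sender", "metabolite_id", "metabolite_name", "sensor_gene",
                 "sensor_class", "receiver", "raw_aggregate", "sensor_mean",
                 "coexpr_score", "null_mean", "comm_score", "p_value", "fdr",
                 "flags")]
  rownames(tab) <- NULL
  attr(tab, "params") <- params
  class(tab) <- c("comm_table", "data.frame")
  tab
}

# Fraction-expressing gate: sender must express at least one producing enzyme
# of the metabolite, and receiver the sensor, in >= min_frac of cells.
.expression_fraction_ok <- function(ctx, min_frac) {
  frac <- rowsum((ctx$X > 0) + 0, ctx$labels)
  frac <- frac[ctx$glev, , drop = FALSE] / ctx$sizes
  prod_by_met <- lapply(ctx$mets, function(m) which(ctx$W[, m] > 0))
  sender_frac <- vapply(seq_len(nrow(ctx$events)), function(i) {
    cols <- prod_by_met[[ctx$pairs$met_idx[ctx$events$pair[i]]]]
    max(frac[ctx$events$sender[i], cols])
  }, numeric(1))
  recv_frac <- frac[ctx$idx_sen]
  sender_frac >= min_frac & recv_frac >= min_frac
}

#' Detected (significant) events of a communication table
#'
#' @param table a `comm_table`.
#' @param fdr_cutoff FDR threshold; defaults to the table's inference cutoff.
#' @param drop_gated drop events flagged `flux_gated` (default `TRUE`).
#' @return the subset of rows defining "detected mCCC".
#' @export
significant_events <- function(table, fdr_cutoff = NULL, drop_gated = TRUE) {
  stopifnot(inherits(table, "comm_table"))
  if (is.null(fdr_cutoff)) {
    p <- attr(table, "params")
    fdr_cutoff <- if (!is.null(p)) p$fdr_cutoff else 0.05
  }
  keep <- table$fdr < fdr_cutoff
  if (drop_gated) keep <- keep & !grepl("flux_gated", table$flags)
  table[keep, , drop = FALSE]
}

#' @export
print.comm_table <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("comm_table: %d scored events", nrow(x)))
  if (!is.null(p)) {
    cat(sprintf(", %d detected at FDR < %g (n_perm = %d, seed = %d)",
                sum(x$fdr < p$fdr_cutoff & !grepl("flux_gated", x$flags)),
                p$fdr_cutoff, p$n_perm, p$seed))
  }
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write / read a communication table as TSV
#'
#' @param table a `comm_table`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_comm_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_comm_table
#' @export
read_comm_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$flags[is.na(tab$flags)] <- ""
  class(tab) <- c("comm_table", "data.frame")
  tab
}
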