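#' Flux matrices: metabolite efflux and influx per cell group
#'
#' Flux estimation itself is out of scope for this package; any external
#' estimator (e.g. a single-cell flux-balance tool) can supply a cell group x
#' metabolite matrix of efflux (secretion) or influx (uptake) scores, treated
#' as relative quantities in the estimator's units.
#'
#' @param values numeric matrix, rows = cell groups, columns = metabolite ids.
#' @param kind `"efflux"` or `"influx"`.
#' @return a `flux_matrix` object.
#' @export
flux_matrix <- function(values, kind = c("efflux", "influx")) {
  kind <- match.arg(kind)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("flux matrix needs group row names and metabolite column names",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("flux matrix values must be finite", call. = FALSE)
  }
  structure(list(kind = kind, values = values), class = "flux_matrix")
}

#' @rdname flux_matrix
#' @param path TSV with cell groups as rows (first column) and metabolite ids
#'   as column headers.
#' @export
read_flux_matrix <- function(path, kind = c("efflux", "influx")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("flux file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  flux_matrix(as.matrix(df), kind)
}

#' @rdname flux_matrix
#' @param fm a `flux_matrix` to write.
#' @export
write_flux_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "flux_matrix"))
  df <- data.frame(group = rownames(fm$values), fm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flux-gate parameters
#'
#' @param percentile percentile (0-100) of the pooled flux scores defining
#'   the threshold; default 25.
#' @param per_metabolite compute the threshold within each metabolite column
#'   instead of pooling the whole matrix (default `FALSE`, pooled).
#' @param keep_gated retain filtered events flagged `flux_gated` instead of
#'   dropping them (default `FALSE`).
#' @return a `flux_gate_params` list.
#' @export
flux_gate_params <- function(percentile = 25, per_metabolite = FALSE,
                             keep_gated = FALSE) {
  stopifnot(percentile >= 0, percentile <= 100)
  structure(list(percentile = percentile, per_metabolite = per_metabolite,
                 keep_gated = keep_gated),
            class = "flux_gate_params")
}

#' Percentile threshold of pooled flux scores
#'
#' Linear-interpolation percentile of the pooled values (the comparison
#' downstream is strictly greater-than, so an all-equal matrix filters
#' everything - a documented degenerate case).
#'
#' @param values numeric vector (a flux matrix pooled over groups and
#'   metabolites).
#' @param q percentile in 0-100.
#' @return the threshold tau.
#' @examples
#' percentile_threshold(c(1, 2, 3, 4), 25)  # 1.75
#' @export
percentile_threshold <- function(values, q) {
  if (length(values) == 0) stop("empty flux values", call. = FALSE)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Gate communication events by metabolite efflux and influx
#'
#' An event is kept only if the sender group's efflux for the metabolite
#' strictly exceeds the efflux threshold and - when the sensor is a
#' transporter or nuclear receptor, i.e. signalling requires uptake - the
#' receiver group's influx strictly exceeds the influx threshold. Surface
#' receptor events are exempt from the influx condition, since the metabolite
#' acts at the cell surface without entering the receiver. Thresholds default
#' to the 25th percentile of each matrix's pooled scores. Scores, p-values
#' and FDR of surviving events are never altered, and FDR is not recomputed
#' after gating.
#'
#' @param table a `comm_table`.
#' @param efflux,influx `flux_matrix` objects covering every (group,
#'   metabolite) in the table; missing entries raise an error naming the keys.
#' @param params a [flux_gate_params()].
#' @return the gated `comm_table`; if `params$keep_gated`, removed events are
#'   retained with `flux_gated` appended to `flags`.
#' @export
apply_flux_filter <- function(table, efflux, influx,
                              params = flux_gate_params()) {
  stopifnot(inherits(table, "comm_table"),
            inherits(efflux, "flux_matrix"), inherits(influx, "flux_matrix"),
            inherits(params, "flux_gate_params"))
  if (efflux$kind != "efflux" || influx$kind != "influx") {
    stop("flux matrices must be of kind 'efflux' and 'influx' respectively",
         call. = FALSE)
  }
  if (nrow(table) == 0) return(table)

  check_cover <- function(fm, groups, what) {
    miss_g <- setdiff(groups, rownames(fm$values))
    miss_m <- setdiff(table$metabolite_id, colnames(fm$values))
    if (length(miss_g) > 0 || length(miss_m) > 0) {
      stop(sprintf("%s matrix is missing %s%s", what,
                   if (length(miss_g)) paste0("group(s): ",
                       paste(miss_g, collapse = ", ")) else "",
                   if (length(miss_m)) paste0(" metabolite(s): ",
                       paste(miss_m, collapse = ", ")) else ""),
           call. = FALSE)
    }
  }
  check_cover(efflux, unique(table$sender), "efflux")
  check_cover(influx, unique(table$receiver), "influx")

  thr <- function(fm, met) {
    if (params$per_metabolite) {
      percentile_threshold(fm$values[, met], params$percentile)
    } else {
      percentile_threshold(as.vector(fm$values), params$percentile)
    }
  }
  tau_e <- if (params$per_metabolite) NULL else thr(efflux, NULL)
  tau_i <- if (params$per_metabolite) NULL else thr(influx, NULL)
  if (!params$per_metabolite &&
      (length(unique(as.vector(efflux$values))) == 1 ||
       length(unique(as.vector(influx$values))) == 1)) {
    warning("all-equal flux scores: the strict threshold filters every event",
            call. = FALSE)
  }

  e_val <- efflux$values[cbind(table$sender, table$metabolite_id)]
  i_val <- influx$values[cbind(table$receiver, table$metabolite_id)]
  if (params$per_metabolite) {
    tau_e <- vapply(table$metabolite_id, function(m) thr(efflux, m), numeric(1))
    tau_i <- vapply(table$metabolite_id, function(m) thr(influx, m), numeric(1))
  }
  needs_influx <- table$sensor_class %in% c("transporter", "nuclear_receptor")
  # strict comparison ("exceeds"); the zero percentile disables trimming at
  # the minimum, so percentile 0 over positive fluxes is the identity
  pass <- function(v, tau) if (params$percentile == 0) v >= tau else v > tau
  keep <- pass(e_val, tau_e) & (!needs_influx | pass(i_val, tau_i))

  params_attr <- attr(table, "params")
  if (params$keep_gated) {
    out <- table
    gated <- !keep
    out$flags[gated] <- ifelse(nzchar(out$flags[gated]),
                               paste0(out$flags[gated], ",flux_gated"),
                               "flux_gated")
  } else {
    out <- table[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "params") <- params_attr
  attr(out, "flux_gate") <- params
  class(out) <- c("comm_table", "data.frame")
  out
}
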