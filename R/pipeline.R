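#' End-to-end inference run with on-disk outputs
#'
#' Reads expression + annotation and a knowledgebase, normalizes, matches
#' genes, infers communication events, optionally applies the flux gate, and
#' writes the result table plus a run-metadata JSON capturing package
#' version, seed, parameters and input checksums, so a run can be reproduced
#' exactly. On any stage error, partial outputs are removed.
#'
#' @param expression_path,genes_path,barcodes_path,annotation_path inputs for
#'   [read_expression()].
#' @param kb_dir directory holding `metabolites.tsv`, `enzymes.tsv`,
#'   `sensors.tsv` (default: the bundled fixture knowledgebase).
#' @param efflux_path,influx_path optional flux matrix TSVs; providing both
#'   switches the flux gate on.
#' @param out_dir output directory (created).
#' @param params an [inference_params()].
#' @param gate a [flux_gate_params()].
#' @param orientation matrix orientation, see [read_expression()].
#' @param normalize normalize the input counts (default `TRUE`; set `FALSE`
#'   for pre-normalized matrices).
#' @param species_mode gene matching mode, see [match_genes_to_dataset()].
#' @return the final `comm_table`, invisibly; files `mccc_events.tsv` and
#'   `run_metadata.json` appear under `out_dir`.
#' @export
run_infer <- function(expression_path, genes_path = NULL,
                      barcodes_path = NULL, annotation_path,
                      kb_dir = system.file("extdata", "kb_mini",
                                           package = "metacomm"),
                      efflux_path = NULL, influx_path = NULL,
                      out_dir, params = inference_params(),
                      gate = flux_gate_params(),
                      orientation = "genes_x_cells",
                      normalize = TRUE,
                      species_mode = "case_insensitive") {
  inputs <- c(expression = expression_path, annotation = annotation_path,
              genes = genes_path, barcodes = barcodes_path,
              efflux = efflux_path, influx = influx_path,
              metabolites = file.path(kb_dir, "metabolites.tsv"),
              enzymes = file.path(kb_dir, "enzymes.tsv"),
              sensors = file.path(kb_dir, "sensors.tsv"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_tsv <- file.path(out_dir, "mccc_events.tsv")
  out_meta <- file.path(out_dir, "run_metadata.json")

  stage <- "read_expression"
  result <- tryCatch({
    ds <- read_expression(expression_path, genes_path, barcodes_path,
                          annotation_path, orientation = orientation)
    if (normalize) {
      stage <- "normalize_expression"
      ds <- normalize_expression(ds)
    } else {
      ds$normalized <- TRUE
    }
    stage <- "load_knowledgebase"
    kb <- load_knowledgebase(file.path(kb_dir, "metabolites.tsv"),
                             file.path(kb_dir, "enzymes.tsv"),
                             file.path(kb_dir, "sensors.tsv"))
    stage <- "match_genes_to_dataset"
    kb <- match_genes_to_dataset(kb, ds$genes, species_mode)
    stage <- "infer_mccc"
    tab <- infer_mccc(ds, kb, params)
    if (!is.null(efflux_path) && !is.null(influx_path)) {
      stage <- "apply_flux_filter"
      tab <- apply_flux_filter(tab, read_flux_matrix(efflux_path, "efflux"),
                               read_flux_matrix(influx_path, "influx"), gate)
    }
    stage <- "write_outputs"
    write_comm_table(tab, out_tsv)
    meta <- list(
      package = "metacomm",
      version = as.character(utils::packageVersion("metacomm")),
      seed = params$seed,
      params = unclass(params),
      flux_gate = if (!is.null(efflux_path)) unclass(gate) else NULL,
      inputs = as.list(inputs),
      input_md5 = as.list(tools::md5sum(inputs)),
      n_events = nrow(tab),
      n_detected = nrow(significant_events(tab)))
    jsonlite::write_json(meta, out_meta, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    tab
  }, error = function(e) {
    unlink(c(out_tsv, out_meta))
    stop(sprintf("run_infer failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Compare communication tables across conditions
#'
#' Assembles the events x conditions score matrix (union of detected events,
#' zero-filled), computes the index of dispersion for every event, selects
#' the top condition-variable fraction, and clusters the z-scored condition
#' profiles by k-means.
#'
#' @param tables list of `comm_table`s or paths to their TSVs (>= 2).
#' @param labels condition labels, one per table.
#' @param top_fraction IOD selection fraction (default 0.05).
#' @param k number of k-means clusters (default 5, capped at the number of
#'   selected events).
#' @param seed RNG seed for clustering.
#' @param out_dir optional directory for TSV reports.
#' @return list: `scores` (condition matrix), `iod` (per-event data frame),
#'   `selected` (top-variable events with achieved IOD cutoff), `clusters`
#'   (from [cluster_events()] on the selected events, `NULL` if fewer than
#'   `k`).
#' @export
run_compare <- function(tables, labels, top_fraction = 0.05, k = 5,
                        seed = 1, out_dir = NULL) {
  if (length(tables) < 2) stop("need >= 2 condition tables", call. = FALSE)
  if (length(labels) != length(tables)) {
    stop("labels must match the number of tables", call. = FALSE)
  }
  tables <- lapply(tables, function(t) {
    if (is.character(t)) read_comm_table(t) else t
  })
  cs <- condition_scores(tables, labels)
  iod_all <- index_of_dispersion(unclass(cs))
  iod_df <- data.frame(event = rownames(cs), iod = unname(iod_all),
                       stringsAsFactors = FALSE)
  sel <- select_variable_events(cs, top_fraction)
  cl <- NULL
  if (nrow(sel) >= 1) {
    sub <- unclass(cs)[sel$event, , drop = FALSE]
    varying <- sub[apply(sub, 1, stats::sd) > 0, , drop = FALSE]
    z <- t(scale(t(varying)))
    # k cannot exceed the number of distinct condition profiles
    k_use <- min(k, nrow(unique(round(z, 12))))
    if (k_use >= 1) cl <- cluster_events(varying, k = k_use, seed = seed)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(data.frame(event = rownames(cs), unclass(cs),
                                  check.names = FALSE),
                       file.path(out_dir, "condition_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(iod_df, file.path(out_dir, "iod.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sel, file.path(out_dir, "variable_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cl)) {
      utils::write.table(data.frame(event = names(cl$clusters),
                                    cluster = cl$clusters),
                         file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(scores = cs, iod = iod_df, selected = sel, clusters = cl)
}

#' Write a synthetic scenario to disk in standard formats
#'
#' Writes MTX + gene/barcode lists, the annotation table, the planted-truth
#' table, efflux/influx TSVs and mock spot proportions into a directory -
#' the on-disk mirror of one simulation, consumable by [run_infer()].
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory.
#' @param kb knowledgebase (default the bundled fixture).
#' @return the directory path, invisibly.
#' @export
write_synthetic_scenario <- function(cfg, dir, kb = fixture_knowledgebase()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_synthetic_dataset(cfg, kb)
  ds <- sim$dataset
  m <- Matrix::Matrix(t(as.matrix(ds$x)), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$genes, file.path(dir, "genes.tsv"))
  writeLines(ds$cells, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(cell_id = ds$cells,
                                group = as.character(ds$groups)),
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- generate_synthetic_flux(sim$truth, seed = cfg$seed)
  write_flux_matrix(fl$efflux, file.path(dir, "efflux.tsv"))
  write_flux_matrix(fl$influx, file.path(dir, "influx.tsv"))
  props <- generate_mock_spatial(sim$truth, seed = cfg$seed)
  utils::write.table(data.frame(spot = rownames(props), props,
                                check.names = FALSE),
                     file.path(dir, "spot_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
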