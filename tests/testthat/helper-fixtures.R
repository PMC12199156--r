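# Shared fixtures: all built in code at test time.

fx_kb <- function() fixture_knowledgebase()

kb_paths <- function() {
  d <- system.file("extdata", "kb_mini", package = "metacomm")
  list(met = file.path(d, "metabolites.tsv"),
       enz = file.path(d, "enzymes.tsv"),
       sen = file.path(d, "sensors.tsv"))
}

# A tiny two-group knowledgebase-aligned dataset: 6 cells, groups A/B of 3,
# expression over a handful of fixture genes, values chosen by hand so that
# scores are non-degenerate. Treated as already normalized.
toy_dataset <- function() {
  genes <- c("GLUL", "GLS", "SLC1A5", "GPT", "SLC7A8", "G6PC1", "HK1",
             "SLC2A1")
  x <- rbind(
    c(4, 1, 0.5, 2, 0.2, 1, 1, 0.8),   # A cells
    c(3, 0, 1.0, 3, 0.1, 2, 0, 0.2),
    c(5, 2, 0.0, 2, 0.4, 1, 2, 0.5),
    c(1, 1, 2.0, 0, 1.5, 0, 1, 1.2),   # B cells
    c(0, 2, 3.0, 1, 2.0, 1, 0, 0.9),
    c(1, 0, 2.5, 0, 1.8, 0, 1, 1.5))
  cells <- sprintf("c%d", 1:6)
  groups <- stats::setNames(rep(c("A", "B"), each = 3), cells)
  expression_dataset(x, groups, genes = genes, cells = cells,
                     normalized = TRUE)
}

# Independent oracle: exhaustive permutation distribution for a 2-group toy.
# Computed with plain loops straight from the knowledgebase tables, not via
# the package's scoring internals.
exhaustive_scores <- function(ds, kb) {
  x <- as.matrix(ds$x)
  gl <- as.character(ds$groups)
  sizes <- table(gl)
  stopifnot(length(sizes) == 2)
  gA <- names(sizes)[1]
  gB <- names(sizes)[2]
  nA <- sizes[[1]]
  idx_all <- utils::combn(nrow(x), nA)

  sen <- kb$sensors[kb$sensors$sensor_gene %in% colnames(x), , drop = FALSE]
  enz <- kb$enzymes[kb$enzymes$gene %in% colnames(x), , drop = FALSE]
  prod_mets <- unique(enz$metabolite_id[enz$direction == "producing"])
  sen <- sen[sen$metabolite_id %in% prod_mets, , drop = FALSE]

  score_assignment <- function(rowsA) {
    means <- list()
    means[[gA]] <- colMeans(x[rowsA, , drop = FALSE])
    means[[gB]] <- colMeans(x[-rowsA, , drop = FALSE])
    out <- list()
    for (p in seq_len(nrow(sen))) {
      m <- sen$metabolite_id[p]
      pg <- enz$gene[enz$metabolite_id == m & enz$direction == "producing"]
      cg <- enz$gene[enz$metabolite_id == m & enz$direction == "consuming"]
      for (s in c(gA, gB)) {
        agg <- mean(means[[s]][pg]) -
          (if (length(cg) > 0) mean(means[[s]][cg]) else 0)
        for (r in c(gA, gB)) {
          key <- paste(s, m, sen$sensor_gene[p], r, sep = "|")
          out[[key]] <- max(agg, 0) * means[[r]][[sen$sensor_gene[p]]]
        }
      }
    }
    unlist(out)
  }

  all_scores <- apply(idx_all, 2, score_assignment)   # events x assignments
  obs <- score_assignment(which(gl == gA))
  list(observed = obs, all = all_scores,
       exhaustive_p = rowMeans(all_scores >= obs))
}

# Build a comm_table by hand for filter/summary unit tests.
manual_comm_table <- function(df) {
  defaults <- list(metabolite_name = "m", raw_aggregate = 1, sensor_mean = 1,
                   coexpr_score = 1, null_mean = 0.5, comm_score = 2,
                   p_value = 0.01, fdr = 0.01, flags = "")
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) {
      df[[nm]] <- if (nrow(df) == 0) defaults[[nm]][0] else defaults[[nm]]
    }
  }
  class(df) <- c("comm_table", "data.frame")
  attr(df, "params") <- inference_params()
  df
}

detected_keys <- function(tab) {
  sig <- significant_events(tab)
  paste(sig$sender, sig$metabolite_id, sig$sensor_gene, sig$receiver,
        sep = "|")
}

# One full-pipeline run on a scenario config: infer + flux gate.
pipeline_run <- function(cfg, n_perm = 1000, seed = cfg$seed) {
  sim <- generate_synthetic_dataset(cfg)
  ds <- normalize_expression(sim$dataset)
  kbm <- match_genes_to_dataset(fx_kb(), ds$genes)
  tab <- infer_mccc(ds, kbm, inference_params(n_perm = n_perm, seed = seed))
  fl <- generate_synthetic_flux(sim$truth, seed = seed)
  gated <- apply_flux_filter(tab, fl$efflux, fl$influx)
  list(sim = sim, table = tab, gated = gated,
       detected = detected_keys(gated), truth = truth_keys(sim$truth))
}
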