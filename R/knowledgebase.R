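#' Metabolite-enzyme-sensor knowledgebase
#'
#' A `metacomm_kb` object bundles the three tables that drive mCCC inference:
#' extracellular metabolites, their producing/consuming enzymes, and their
#' sensor proteins (cell-surface transporters, cell-surface receptors, nuclear
#' receptors). The package ships a miniature fixture knowledgebase under
#' `system.file("extdata", "kb_mini", package = "metacomm")`; the full curated
#' knowledgebase distributed with the original resource (432 partners by its
#' release notes, 440 in a later revision) loads through the same reader.
#'
#' @name metacomm_kb
#' @keywords internal
NULL

.sensor_classes <- c("transporter", "surface_receptor", "nuclear_receptor")

# Case-insensitive synonyms seen across curation sources (keys in space form).
.sensor_class_synonyms <- c(
  "transporter"              = "transporter",
  "surface transporter"      = "transporter",
  "cell surface transporter" = "transporter",
  "surface receptor"         = "surface_receptor",
  "cell surface receptor"    = "surface_receptor",
  "receptor"                 = "surface_receptor",
  "nuclear receptor"         = "nuclear_receptor"
)

.normalize_sensor_class <- function(x) {
  key <- tolower(trimws(gsub("[-_]+", " ", x)))
  unname(.sensor_class_synonyms[key])
}

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Load a metabolite-enzyme-sensor knowledgebase from delimited tables
#'
#' Reads the three tab-delimited tables (metabolites, enzyme links, sensor
#' pairs), validates them against the knowledgebase schema, and returns a
#' `metacomm_kb` object. Enzyme or sensor rows whose `metabolite_id` does not
#' resolve to a metabolite record are rejected and reported via the
#' `rejected` component (they are never silently dropped). Duplicate
#' (metabolite, sensor) rows contributed by several sources are merged with
#' their sources concatenated, so multi-source pairs can be counted as their
#' own provenance category. Metabolites lacking either a producing enzyme or a
#' sensor are kept but flagged inactive for inference.
#'
#' @param metabolite_table path to a TSV with columns `metabolite_id`, `name`,
#'   `chem_class`, `extracellular`.
#' @param enzyme_table path to a TSV with columns `metabolite_id`, `gene`,
#'   `direction` (`producing` or `consuming`).
#' @param sensor_table path to a TSV with columns `metabolite_id`,
#'   `sensor_gene`, `sensor_class`, `source`. Sensor classes are matched
#'   case-insensitively against common synonyms (e.g. "cell surface receptor").
#' @return A `metacomm_kb` list with components `metabolites`, `enzymes`,
#'   `sensors` (data frames) and `rejected` (rows that failed referential
#'   checks, with a `reason` column).
#' @examples
#' kb_dir <- system.file("extdata", "kb_mini", package = "metacomm")
#' kb <- load_knowledgebase(file.path(kb_dir, "metabolites.tsv"),
#'                          file.path(kb_dir, "enzymes.tsv"),
#'                          file.path(kb_dir, "sensors.tsv"))
#' nrow(kb$sensors)
#' @export
load_knowledgebase <- function(metabolite_table, enzyme_table, sensor_table) {
  mets <- .read_tsv(metabolite_table,
                    c("metabolite_id", "name", "chem_class", "extracellular"),
                    "metabolite")
  enz <- .read_tsv(enzyme_table, c("metabolite_id", "gene", "direction"),
                   "enzyme")
  sen <- .read_tsv(sensor_table,
                   c("metabolite_id", "sensor_gene", "sensor_class", "source"),
                   "sensor")

  if (anyDuplicated(mets$metabolite_id)) {
    stop("duplicate metabolite_id in metabolite table: ",
         paste(unique(mets$metabolite_id[duplicated(mets$metabolite_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(mets$name))) {
    stop("metabolite table contains empty names", call. = FALSE)
  }
  mets$extracellular <- as.logical(mets$extracellular)

  if (nrow(enz) > 0) {
    bad_dir <- !(enz$direction %in% c("producing", "consuming"))
    if (any(bad_dir)) {
      stop("enzyme table: direction must be 'producing' or 'consuming'; ",
           "offending rows: ", paste(which(bad_dir), collapse = ", "),
           call. = FALSE)
    }
    enz <- unique(enz[, c("metabolite_id", "gene", "direction")])
  }

  if (nrow(sen) > 0) {
    cls <- .normalize_sensor_class(sen$sensor_class)
    if (anyNA(cls)) {
      bad <- which(is.na(cls))
      stop("sensor table: unknown sensor_class token(s) ",
           paste(sprintf("'%s' (row %d)", sen$sensor_class[bad], bad),
                 collapse = ", "), call. = FALSE)
    }
    sen$sensor_class <- cls
  }

  # referential integrity: reject, report, never silently drop
  rejected <- data.frame(table = character(), metabolite_id = character(),
                         gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (nrow(enz) > 0) {
    orphan <- !(enz$metabolite_id %in% mets$metabolite_id)
    if (any(orphan)) {
      rejected <- rbind(rejected, data.frame(
        table = "enzymes", metabolite_id = enz$metabolite_id[orphan],
        gene = enz$gene[orphan], reason = "unresolved metabolite_id",
        stringsAsFactors = FALSE))
      enz <- enz[!orphan, , drop = FALSE]
    }
  }
  if (nrow(sen) > 0) {
    orphan <- !(sen$metabolite_id %in% mets$metabolite_id)
    if (any(orphan)) {
      rejected <- rbind(rejected, data.frame(
        table = "sensors", metabolite_id = sen$metabolite_id[orphan],
        gene = sen$sensor_gene[orphan], reason = "unresolved metabolite_id",
        stringsAsFactors = FALSE))
      sen <- sen[!orphan, , drop = FALSE]
    }
    # merge duplicate (metabolite, sensor) pairs across sources
    key <- paste(sen$metabolite_id, sen$sensor_gene, sep = "\r")
    if (anyDuplicated(key)) {
      agg_src <- tapply(sen$source, key, function(s)
        paste(sort(unique(s), method = "radix"), collapse = ";"))
      first <- !duplicated(key)
      sen <- sen[first, , drop = FALSE]
      sen$source <- unname(agg_src[paste(sen$metabolite_id, sen$sensor_gene,
                                         sep = "\r")])
    }
  }
  if (nrow(rejected) > 0) {
    warning(sprintf("%d knowledgebase row(s) rejected (unresolved metabolite_id); see $rejected",
                    nrow(rejected)), call. = FALSE)
  }

  has_prod <- mets$metabolite_id %in% enz$metabolite_id[enz$direction == "producing"]
  has_sens <- mets$metabolite_id %in% sen$metabolite_id
  mets$active <- has_prod & has_sens

  rownames(mets) <- rownames(enz) <- rownames(sen) <- NULL
  structure(list(metabolites = mets, enzymes = enz, sensors = sen,
                 rejected = rejected),
            class = "metacomm_kb")
}

#' Write a knowledgebase back to delimited tables
#'
#' Inverse of [load_knowledgebase()]: writes the three TSV tables into a
#' directory so that reloading reproduces the same records.
#'
#' @param kb a `metacomm_kb` object.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_knowledgebase <- function(kb, dir) {
  stopifnot(inherits(kb, "metacomm_kb"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mets <- kb$metabolites
  mets$active <- NULL
  utils::write.table(mets, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kb$enzymes, file.path(dir, "enzymes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kb$sensors, file.path(dir, "sensors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load the bundled miniature fixture knowledgebase
#'
#' @return a `metacomm_kb` with 11 metabolites covering all three sensor
#'   classes, used throughout the examples, tests and simulations.
#' @export
fixture_knowledgebase <- function() {
  d <- system.file("extdata", "kb_mini", package = "metacomm")
  load_knowledgebase(file.path(d, "metabolites.tsv"),
                     file.path(d, "enzymes.tsv"),
                     file.path(d, "sensors.tsv"))
}

#' @export
print.metacomm_kb <- function(x, ...) {
  cat(sprintf("metacomm knowledgebase: %d metabolites (%d active), %d enzyme links, %d sensor pairs\n",
              nrow(x$metabolites), sum(x$metabolites$active),
              nrow(x$enzymes), nrow(x$sensors)))
  invisible(x)
}

#' Summarize a knowledgebase
#'
#' Counts and fractions of metabolite-sensor pairs by sensor class, by
#' provenance source, and of metabolites by chemical class, plus the
#' per-metabolite sensor counts and per-sensor metabolite counts used to
#' describe a knowledgebase release (e.g. class fractions of roughly
#' 52/36/12 percent transporter / surface receptor / nuclear receptor in the
#' full curated resource).
#'
#' @param kb a `metacomm_kb`.
#' @return a list with components `n_pairs`, `n_metabolites`,
#'   `n_active_metabolites`, `by_class`, `by_source`, `by_chem_class`
#'   (each a data frame with `count` and `fraction`), `sensors_per_metabolite`
#'   and `metabolites_per_sensor` (named integer vectors).
#' @export
summarize_knowledgebase <- function(kb) {
  stopifnot(inherits(kb, "metacomm_kb"))
  sen <- kb$sensors
  n <- nrow(sen)
  tab_df <- function(v) {
    if (length(v) == 0) {
      return(data.frame(level = character(), count = integer(),
                        fraction = numeric(), stringsAsFactors = FALSE))
    }
    t <- sort(table(v), decreasing = TRUE)
    data.frame(level = names(t), count = as.integer(t),
               fraction = as.integer(t) / length(v),
               stringsAsFactors = FALSE)
  }
  # pairs carrying several sources count once under "multiple"
  src <- sen$source
  src[grepl(";", src)] <- "multiple"
  list(
    n_pairs = n,
    n_metabolites = nrow(kb$metabolites),
    n_active_metabolites = sum(kb$metabolites$active),
    by_class = tab_df(sen$sensor_class),
    by_source = tab_df(src),
    by_chem_class = tab_df(kb$metabolites$chem_class),
    sensors_per_metabolite = if (n > 0) table(sen$metabolite_id) else table(character()),
    metabolites_per_sensor = if (n > 0) table(sen$sensor_gene) else table(character())
  )
}

#' Restrict a knowledgebase to genes present in a dataset
#'
#' Reconciles knowledgebase gene symbols with a dataset's gene list, either
#' exactly or case-insensitively (the latter covers applying a human-curated
#' knowledgebase to mouse data, where symbols differ only by case). Enzyme
#' links and sensor pairs whose gene is absent are removed and reported;
#' matched symbols are rewritten to the dataset's spelling so downstream
#' lookups are direct. Metabolites left without a producing enzyme or without
#' a sensor become inactive.
#'
#' @param kb a `metacomm_kb`.
#' @param dataset_genes character vector of gene symbols in the expression
#'   dataset.
#' @param species_mode `"exact"` or `"case_insensitive"`.
#' @return the restricted `metacomm_kb`, with an `unmatched` attribute: a data
#'   frame listing knowledgebase genes that found no dataset match.
#' @export
match_genes_to_dataset <- function(kb, dataset_genes,
                                   species_mode = c("case_insensitive", "exact")) {
  stopifnot(inherits(kb, "metacomm_kb"))
  species_mode <- match.arg(species_mode)
  if (length(dataset_genes) == 0) {
    stop("dataset_genes must be non-empty", call. = FALSE)
  }
  lookup <- function(g) {
    if (species_mode == "exact") {
      ifelse(g %in% dataset_genes, g, NA_character_)
    } else {
      idx <- match(toupper(g), toupper(dataset_genes))
      dataset_genes[idx]
    }
  }
  enz <- kb$enzymes
  sen <- kb$sensors
  enz_match <- lookup(enz$gene)
  sen_match <- lookup(sen$sensor_gene)

  unmatched <- rbind(
    if (any(is.na(enz_match))) data.frame(
      table = "enzymes", metabolite_id = enz$metabolite_id[is.na(enz_match)],
      gene = enz$gene[is.na(enz_match)], stringsAsFactors = FALSE),
    if (any(is.na(sen_match))) data.frame(
      table = "sensors", metabolite_id = sen$metabolite_id[is.na(sen_match)],
      gene = sen$sensor_gene[is.na(sen_match)], stringsAsFactors = FALSE)
  )
  if (is.null(unmatched)) {
    unmatched <- data.frame(table = character(), metabolite_id = character(),
                            gene = character(), stringsAsFactors = FALSE)
  }

  enz <- enz[!is.na(enz_match), , drop = FALSE]
  enz$gene <- enz_match[!is.na(enz_match)]
  sen <- sen[!is.na(sen_match), , drop = FALSE]
  sen$sensor_gene <- sen_match[!is.na(sen_match)]
  enz <- unique(enz)
  key <- paste(sen$metabolite_id, sen$sensor_gene)
  sen <- sen[!duplicated(key), , drop = FALSE]

  if (nrow(sen) == 0) {
    stop("no knowledgebase sensor gene matches the dataset; inference impossible",
         call. = FALSE)
  }

  mets <- kb$metabolites
  has_prod <- mets$metabolite_id %in% enz$metabolite_id[enz$direction == "producing"]
  has_sens <- mets$metabolite_id %in% sen$metabolite_id
  mets$active <- has_prod & has_sens
  rownames(enz) <- rownames(sen) <- NULL

  out <- structure(list(metabolites = mets, enzymes = enz, sensors = sen,
                        rejected = kb$rejected),
                   class = "metacomm_kb")
  attr(out, "unmatched") <- unmatched
  out
}
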