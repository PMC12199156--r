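test_that("fixture knowledgebase loads with all invariants satisfied", {
  kb <- fx_kb()
  expect_s3_class(kb, "metacomm_kb")
  expect_equal(nrow(kb$metabolites), 11)
  expect_equal(nrow(kb$sensors), 17)
  expect_true(all(kb$sensors$sensor_class %in%
                    c("transporter", "surface_receptor", "nuclear_receptor")))
  # referential integrity
  expect_true(all(kb$enzymes$metabolite_id %in% kb$metabolites$metabolite_id))
  expect_true(all(kb$sensors$metabolite_id %in% kb$metabolites$metabolite_id))
  # every fixture metabolite has a producing enzyme and a sensor
  expect_true(all(kb$metabolites$active))
  expect_equal(nrow(kb$rejected), 0)
})

test_that("sensor class synonyms are mapped case-insensitively", {
  d <- withr::local_tempdir()
  writeLines(c("metabolite_id\tname\tchem_class\textracellular",
               "M1\tmet one\tLipids\tTRUE"),
             file.path(d, "m.tsv"))
  writeLines(c("metabolite_id\tgene\tdirection", "M1\tENZ1\tproducing"),
             file.path(d, "e.tsv"))
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "M1\tS1\tCell Surface Receptor\tliterature",
               "M1\tS2\tTRANSPORTER\tRecon2",
               "M1\tS3\tnuclear-receptor\tWikipedia"),
             file.path(d, "s.tsv"))
  kb <- load_knowledgebase(file.path(d, "m.tsv"), file.path(d, "e.tsv"),
                           file.path(d, "s.tsv"))
  expect_setequal(kb$sensors$sensor_class,
                  c("surface_receptor", "transporter", "nuclear_receptor"))
})

test_that("header-only tables give an empty knowledgebase and zero summary", {
  d <- withr::local_tempdir()
  writeLines("metabolite_id\tname\tchem_class\textracellular",
             file.path(d, "m.tsv"))
  writeLines("metabolite_id\tgene\tdirection", file.path(d, "e.tsv"))
  writeLines("metabolite_id\tsensor_gene\tsensor_class\tsource",
             file.path(d, "s.tsv"))
  kb <- load_knowledgebase(file.path(d, "m.tsv"), file.path(d, "e.tsv"),
                           file.path(d, "s.tsv"))
  expect_equal(nrow(kb$sensors), 0)
  expect_equal(nrow(kb$enzymes), 0)
  s <- summarize_knowledgebase(kb)
  expect_equal(s$n_pairs, 0)
  expect_equal(nrow(s$by_class), 0)
})

test_that("schema and validation errors name the offending parts", {
  d <- withr::local_tempdir()
  p <- kb_paths()
  expect_error(load_knowledgebase(file.path(d, "nope.tsv"), p$enz, p$sen),
               "not found")
  # missing column
  writeLines(c("metabolite_id\tname", "M1\tx"), file.path(d, "m.tsv"))
  expect_error(load_knowledgebase(file.path(d, "m.tsv"), p$enz, p$sen),
               "chem_class")
  # bad sensor class token
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "HMDB0000641\tS1\tmystery\tliterature"),
             file.path(d, "s.tsv"))
  expect_error(load_knowledgebase(p$met, p$enz, file.path(d, "s.tsv")),
               "mystery")
  # bad enzyme direction
  writeLines(c("metabolite_id\tgene\tdirection",
               "HMDB0000641\tGLUL\tsideways"),
             file.path(d, "e.tsv"))
  expect_error(load_knowledgebase(p$met, file.path(d, "e.tsv"), p$sen),
               "direction")
})

test_that("rows with unresolved metabolite ids are rejected with a report", {
  d <- withr::local_tempdir()
  p <- kb_paths()
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "HMDB0000641\tSLC1A5\ttransporter\tliterature",
               "NOT_A_MET\tXYZ\ttransporter\tliterature"),
             file.path(d, "s.tsv"))
  expect_warning(
    kb <- load_knowledgebase(p$met, p$enz, file.path(d, "s.tsv")),
    "rejected")
  expect_equal(nrow(kb$rejected), 1)
  expect_equal(kb$rejected$metabolite_id, "NOT_A_MET")
  expect_false("NOT_A_MET" %in% kb$sensors$metabolite_id)
})

test_that("duplicate pairs from multiple sources merge into one record", {
  d <- withr::local_tempdir()
  p <- kb_paths()
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "HMDB0000641\tSLC1A5\ttransporter\tliterature",
               "HMDB0000641\tSLC1A5\ttransporter\tRecon2",
               "HMDB0000122\tSLC2A1\ttransporter\tRecon2"),
             file.path(d, "s.tsv"))
  kb <- load_knowledgebase(p$met, p$enz, file.path(d, "s.tsv"))
  expect_equal(nrow(kb$sensors), 2)
  merged <- kb$sensors$source[kb$sensors$sensor_gene == "SLC1A5"]
  expect_equal(merged, "Recon2;literature")
  s <- summarize_knowledgebase(kb)
  expect_true("multiple" %in% s$by_source$level)
})

test_that("summary counts are partition-consistent and fractions sum to 1", {
  kb <- fx_kb()
  s <- summarize_knowledgebase(kb)
  expect_equal(sum(s$by_class$count), s$n_pairs)
  expect_equal(sum(s$by_source$count), s$n_pairs)
  expect_equal(sum(s$by_class$fraction), 1)
  expect_equal(sum(s$by_source$fraction), 1)
  expect_equal(sum(s$by_chem_class$count), s$n_metabolites)
  expect_equal(sum(s$sensors_per_metabolite), s$n_pairs)
  expect_equal(sum(s$metabolites_per_sensor), s$n_pairs)
})

test_that("one pair of each class gives fractions of one third", {
  d <- withr::local_tempdir()
  writeLines(c("metabolite_id\tname\tchem_class\textracellular",
               "M1\tm1\tLipids\tTRUE"), file.path(d, "m.tsv"))
  writeLines(c("metabolite_id\tgene\tdirection", "M1\tE1\tproducing"),
             file.path(d, "e.tsv"))
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "M1\tS1\ttransporter\ta",
               "M1\tS2\tsurface_receptor\tb",
               "M1\tS3\tnuclear_receptor\tc"), file.path(d, "s.tsv"))
  kb <- load_knowledgebase(file.path(d, "m.tsv"), file.path(d, "e.tsv"),
                           file.path(d, "s.tsv"))
  s <- summarize_knowledgebase(kb)
  expect_equal(s$by_class$fraction, rep(1 / 3, 3))
})

test_that("write/load round-trip reproduces the same records", {
  kb <- fx_kb()
  d <- withr::local_tempdir()
  write_knowledgebase(kb, d)
  kb2 <- load_knowledgebase(file.path(d, "metabolites.tsv"),
                            file.path(d, "enzymes.tsv"),
                            file.path(d, "sensors.tsv"))
  key <- function(df) do.call(paste, c(df, sep = "|"))
  expect_setequal(key(kb2$metabolites), key(kb$metabolites))
  expect_setequal(key(kb2$enzymes), key(kb$enzymes))
  expect_setequal(key(kb2$sensors), key(kb$sensors))
})

test_that("gene matching handles case modes, reports, and is idempotent", {
  kb <- fx_kb()
  genes <- c("Slc1a5", "Glul", "Gls", "Gpt", "Slc7a8")
  m <- match_genes_to_dataset(kb, genes, "case_insensitive")
  expect_true("Slc1a5" %in% m$sensors$sensor_gene)  # rewritten to dataset case
  expect_true(all(m$sensors$sensor_gene %in% genes))
  expect_true(all(m$enzymes$gene %in% genes))
  # exact mode flags the unmatched pair
  e <- match_genes_to_dataset(kb, c("SLC1A5", "GLUL", "GPT", "SLC7A8"),
                              "exact")
  unmatched <- attr(e, "unmatched")
  expect_true("SLC38A2" %in% unmatched$gene)
  expect_false("SLC38A2" %in% e$sensors$sensor_gene)
  # inactive flag: metabolite with sensor but no producing enzyme left
  expect_false(
    e$metabolites$active[e$metabolites$metabolite_id == "HMDB0000122"])
  # idempotence
  m2 <- match_genes_to_dataset(m, genes, "case_insensitive")
  expect_equal(m2$sensors, m$sensors)
  expect_equal(m2$enzymes, m$enzymes)
  expect_equal(m2$metabolites, m$metabolites)
  # no resolvable sensors at all is a hard error
  expect_error(match_genes_to_dataset(kb, c("ACTB", "GAPDH"), "exact"),
               "impossible")
})

test_that("restricting to 2 of 3 sensors reports exactly the missing one", {
  d <- withr::local_tempdir()
  writeLines(c("metabolite_id\tname\tchem_class\textracellular",
               "M1\tm1\tLipids\tTRUE"), file.path(d, "m.tsv"))
  writeLines(c("metabolite_id\tgene\tdirection", "M1\tE1\tproducing"),
             file.path(d, "e.tsv"))
  writeLines(c("metabolite_id\tsensor_gene\tsensor_class\tsource",
               "M1\tS1\ttransporter\ta",
               "M1\tS2\tsurface_receptor\tb",
               "M1\tS3\tnuclear_receptor\tc"), file.path(d, "s.tsv"))
  kb <- load_knowledgebase(file.path(d, "m.tsv"), file.path(d, "e.tsv"),
                           file.path(d, "s.tsv"))
  m <- match_genes_to_dataset(kb, c("E1", "S1", "S2"), "exact")
  expect_equal(nrow(m$sensors), 2)
  rep <- attr(m, "unmatched")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$gene, "S3")
})
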