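test_that("colocalization scores are rank correlations with tie handling", {
  props <- cbind(a = c(0.1, 0.2, 0.3, 0.4),
                 b = c(0.2, 0.1, 0.4, 0.3),
                 c = c(0.1, 0.2, 0.3, 0.4),
                 d = c(0.4, 0.3, 0.2, 0.1))
  rho <- colocalization_scores(props)
  expect_equal(rho["a", "b"], 0.6)
  expect_equal(rho["a", "c"], 1)
  expect_equal(rho["a", "d"], -1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  # invariant to monotone transforms
  rho2 <- colocalization_scores(props^3)
  expect_equal(rho2, rho)
  # constant vectors have undefined correlation
  rho3 <- colocalization_scores(cbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_true(is.na(rho3["a", "b"]))
  expect_error(colocalization_scores(props[1:2, ]), "3 spots")
})

test_that("recapture ratios follow the set definitions", {
  expect_equal(recapture_ratios(c("A", "B", "C"), c("B", "C", "D")),
               c(over_total = 2 / 3, over_original = 2 / 3))
  expect_equal(recapture_ratios(c("A", "B"), c("A", "B")),
               c(over_total = 1, over_original = 1))
  expect_equal(recapture_ratios(c("A"), c("B")),
               c(over_total = 0, over_original = 0))
  r <- recapture_ratios(character(0), c("A"))
  expect_true(is.na(r["over_total"]))
  expect_equal(unname(r["over_original"]), 0)
  # symmetry under exchanging the two sets
  a <- c("A", "B", "C", "E")
  b <- c("B", "C", "D")
  expect_equal(unname(recapture_ratios(a, b)["over_total"]),
               unname(recapture_ratios(b, a)["over_original"]))
})

test_that("down-sampling is exact, label-preserving and deterministic", {
  set.seed(1)
  x <- matrix(rpois(2000, 2), nrow = 100,
              dimnames = list(sprintf("c%d", 1:100), sprintf("g%d", 1:20)))
  ds <- expression_dataset(x, stats::setNames(rep(c("A", "B"), 50),
                                              rownames(x)))
  expect_identical(downsample_cells(ds, 1, seed = 1), ds)
  half <- downsample_cells(ds, 0.5, seed = 7)
  expect_equal(length(half$cells), 50)
  expect_identical(downsample_cells(ds, 0.5, seed = 7)$cells, half$cells)
  expect_false(identical(downsample_cells(ds, 0.5, seed = 8)$cells,
                         half$cells))
  expect_equal(as.character(half$groups),
               as.character(ds$groups[half$cells]))
})

test_that("noise injection conserves reads exactly and is deterministic", {
  set.seed(2)
  x <- matrix(rpois(500, 2), nrow = 25,
              dimnames = list(sprintf("c%d", 1:25), sprintf("g%d", 1:20)))
  ds <- expression_dataset(x, stats::setNames(rep(c("A", "B", "C", "D", "E"),
                                                  5), rownames(x)))
  expect_identical(inject_noise(ds, 0), ds)
  total <- sum(x)
  noisy <- inject_noise(ds, 1, seed = 3)
  expect_equal(sum(noisy$x), 2 * total)
  noisy2 <- inject_noise(ds, 0.37, seed = 3)
  expect_equal(sum(noisy2$x), total + ceiling(0.37 * total))
  expect_identical(as.matrix(inject_noise(ds, 1, seed = 3)$x),
                   as.matrix(noisy$x))
  nd <- normalize_expression(ds)
  expect_error(inject_noise(nd, 1), "raw read counts")
})

test_that("index of dispersion is population variance over mean", {
  expect_equal(index_of_dispersion(c(2, 2, 2, 2)), 0)
  expect_equal(index_of_dispersion(c(0, 0, 0, 4)), 3)
  expect_true(is.na(index_of_dispersion(c(0, 0, 0))))
  # permutation invariance and linear scaling
  v <- c(0.3, 1.7, 0.9, 2.4)
  expect_equal(index_of_dispersion(v), index_of_dispersion(rev(v)))
  expect_equal(index_of_dispersion(5 * v), 5 * index_of_dispersion(v))
  # matrix form is row-wise
  m <- rbind(c(2, 2, 2, 2), c(0, 0, 0, 4))
  expect_equal(unname(index_of_dispersion(m)), c(0, 3))
  expect_error(index_of_dispersion(matrix(1, 2, 1)), "2 conditions")
})

test_that("variable-event selection takes the top fraction with ties", {
  set.seed(4)
  cs <- matrix(1, nrow = 100, ncol = 4,
               dimnames = list(sprintf("e%d", 1:100), letters[1:4]))
  # 5 planted variable events among 95 constant ones
  planted <- sprintf("e%d", 1:5)
  cs[planted, ] <- cs[planted, ] * matrix(c(0.1, 1, 2, 5), 5, 4,
                                          byrow = TRUE)
  class(cs) <- c("condition_scores", class(cs))
  sel <- select_variable_events(cs, 0.05)
  expect_setequal(sel$event, planted)
  expect_true(all(sel$iod > 0))
  expect_equal(attr(sel, "iod_cutoff"), min(sel$iod))
  # boundary ties are all included
  cs2 <- matrix(c(rep(c(0, 8), 5), rep(c(1, 2), 35)), ncol = 2,
                byrow = TRUE, dimnames = list(sprintf("t%d", 1:40), NULL))
  sel2 <- select_variable_events(cs2, 0.05)   # ceil(0.05*40) = 2, 5 tied
  expect_equal(nrow(sel2), 5)
})

test_that("clustering separates opposite condition patterns", {
  set.seed(5)
  up <- matrix(rep(c(0, 0, 2, 2), each = 10), nrow = 10) +
    matrix(rnorm(40, sd = 0.05), 10)
  down <- matrix(rep(c(2, 2, 0, 0), each = 10), nrow = 10) +
    matrix(rnorm(40, sd = 0.05), 10)
  m <- rbind(up, down)
  rownames(m) <- sprintf("e%d", 1:20)
  cl <- cluster_events(m, k = 2, seed = 1)
  expect_equal(length(unique(cl$clusters[1:10])), 1)
  expect_equal(length(unique(cl$clusters[11:20])), 1)
  expect_false(cl$clusters[1] == cl$clusters[11])
  # z-scored rows have mean 0 and sd 1
  expect_equal(unname(rowMeans(cl$zscores)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(cl$zscores, 1, sd)), rep(1, 20),
               tolerance = 1e-12)
  # k = 1 puts everything together; constant rows are excluded
  m2 <- rbind(m, const = rep(3, 4))
  cl1 <- cluster_events(m2, k = 1, seed = 1)
  expect_equal(unname(unique(cl1$clusters)), 1)
  expect_equal(cl1$excluded, "const")
  expect_error(cluster_events(m, k = 50, seed = 1), "exceeds")
})

test_that("network summary sums -log10 FDR per directed pair", {
  tab <- manual_comm_table(data.frame(
    sender = c("A", "A", "B"), receiver = c("B", "B", "A"),
    metabolite_id = "M1", sensor_gene = c("S1", "S2", "S1"),
    sensor_class = "transporter", stringsAsFactors = FALSE))
  tab$fdr <- c(0.01, 0.1, 0.1)
  net <- summarize_network(tab, significant_only = FALSE)
  ab <- net[net$sender == "A" & net$receiver == "B", ]
  expect_equal(ab$n_events, 2L)
  expect_equal(ab$strength, 3)
  ba <- net[net$sender == "B", ]
  expect_equal(ba$strength, 1)
  expect_equal(sum(net$n_events), 3)
  # empty input gives an empty summary
  empty <- manual_comm_table(data.frame(
    sender = character(), receiver = character(),
    metabolite_id = character(), sensor_gene = character(),
    sensor_class = character(), stringsAsFactors = FALSE))
  expect_equal(nrow(summarize_network(empty)), 0)
})

test_that("condition scores zero-fill absent events and drive IOD ranking", {
  t1 <- manual_comm_table(data.frame(
    sender = c("A", "A"), metabolite_id = "M1",
    sensor_gene = c("S1", "S2"), sensor_class = "transporter",
    receiver = "B", stringsAsFactors = FALSE))
  t1$comm_score <- c(4, 2)
  t2 <- manual_comm_table(data.frame(
    sender = "A", metabolite_id = "M1", sensor_gene = "S1",
    sensor_class = "transporter", receiver = "B",
    stringsAsFactors = FALSE))
  t2$comm_score <- 4
  cs <- condition_scores(list(t1, t2), c("x", "y"))
  expect_equal(dim(cs), c(2, 2))
  expect_equal(unname(unclass(cs)["A|M1|S2|B", ]), c(2, 0))
  # identical tables: zero IOD everywhere, nothing selected as variable
  cs_same <- condition_scores(list(t1, t1), c("x", "y"))
  expect_true(all(index_of_dispersion(unclass(cs_same)) == 0))
  expect_equal(nrow(select_variable_events(cs_same, 0.05)), 0)
  expect_error(condition_scores(list(t1), "x"), ">= 2")
})

test_that("communication correlates with mock colocalization of planted pairs", {
  s <- 77
  cfg <- spatial_scenario(seed = s)
  sim <- generate_synthetic_dataset(cfg)
  ds <- normalize_expression(sim$dataset)
  kbm <- match_genes_to_dataset(fx_kb(), ds$genes)
  tab <- infer_mccc(ds, kbm, inference_params(n_perm = 5000, seed = s))
  props <- generate_mock_spatial(sim$truth, n_spots = 200,
                                 colocalization_strength = 0.9,
                                 scale_by_fold = TRUE, seed = s)
  coloc <- colocalization_scores(props)
  cc <- comm_coloc_correlation(tab, coloc, min_pairs = 5)
  expect_gt(nrow(cc), 0)
  expect_true(all(cc$n_pairs >= 5))
  expect_gt(attr(cc, "median_rho"), 0.2)
  # a metabolite mediating fewer than min_pairs pairs is excluded
  cc10 <- suppressWarnings(comm_coloc_correlation(tab, coloc,
                                                  min_pairs = 10))
  expect_equal(nrow(cc10), 0)
  # shuffling spot positions destroys the association: medians center at 0
  set.seed(s)
  null_medians <- replicate(5, {
    ps <- apply(props, 2, sample)
    rownames(ps) <- rownames(props)
    attr(comm_coloc_correlation(tab, colocalization_scores(ps),
                                min_pairs = 5), "median_rho")
  })
  expect_lt(abs(mean(null_medians)), 0.45)
  expect_lt(mean(null_medians), attr(cc, "median_rho"))
})
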