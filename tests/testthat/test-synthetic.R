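small_truth <- function(seed = 1, ...) {
  sim_truth(seed = seed,
            venn_counts = list(core = 12, all_R_some_E = 4, some_R_all_E = 3,
                               some_some = 10, R_only = 5, E_only = 6),
            reaction_counts = list(core = 9, shared = 4, R_only = 1,
                                   E_only = 3),
            marker_length = 120, ...)
}

test_that("generators are pure functions of parameters and seed", {
  t1 <- small_truth(seed = 5)
  a <- generate_pangenome(t1); b <- generate_pangenome(t1)
  expect_identical(a$clusters, b$clusters)
  expect_identical(generate_utilization(t1)$util,
                   generate_utilization(t1)$util)
  expect_identical(generate_traits(t1), generate_traits(t1))
  expect_identical(
    generate_alignment("ACGTACGT", 5, 0.2, seed = 3),
    generate_alignment("ACGTACGT", 5, 0.2, seed = 3))
  # a different seed changes the draw
  expect_false(identical(generate_utilization(small_truth(seed = 6))$util,
                         generate_utilization(t1)$util))
})

test_that("exact planting is recovered by the partition", {
  t1 <- small_truth(seed = 2)
  pg <- generate_pangenome(t1)
  pm <- presence_from_clusters(pg$clusters, names(pg$labels))
  v <- partition_compartments(pm, pg$labels)
  expect_equal(venn_cell(v, "all", "all"), 12L)
  expect_equal(venn_cell(v, "all", "some"), 4L)
  expect_equal(venn_cell(v, "some", "all"), 3L)
  expect_equal(venn_cell(v, "some", "some"), 10L)
  expect_equal(venn_cell(v, "some", "none"), 5L)
  expect_equal(venn_cell(v, "none", "some"), 6L)
  expect_equal(v$total, 40L)

  rx <- generate_reactions(t1)
  rv <- reaction_venn(rx$reactions, rx$labels)
  expect_equal(rv$core, 9L)
  expect_equal(rv$shared, 4L)
  expect_equal(rv$rhizosphere_only, 1L)
  expect_equal(rv$endosphere_only, 3L)
  expect_equal(rv$differential, 8L)
})

test_that("impossible plantings are rejected", {
  # 'some' occupancy cannot exist in a one-genome compartment
  t_bad <- sim_truth(seed = 1, n_R = 1,
                     venn_counts = list(core = 2, R_only = 1))
  expect_error(generate_pangenome(t_bad), "size 1")
  expect_error(sim_truth(seed = 1, mu = 2), "mu")
  expect_error(sim_truth(seed = 1, prediction_error_rate = -0.1),
               "error_rate")
  expect_error(sim_truth(seed = 1, nonsense = 1), "unknown")
})

test_that("bernoulli mode with no accessory genes is pure core", {
  t0 <- small_truth(seed = 3, core_size = 15, accessory_size = 0)
  pg <- generate_pangenome(t0, mode = "bernoulli")
  pm <- presence_from_clusters(pg$clusters, names(pg$labels))
  v <- partition_compartments(pm, pg$labels)
  expect_equal(venn_cell(v, "all", "all"), 15L)
  expect_equal(v$total, 15L)
})

test_that("utilization generator honours class fractions and layout", {
  sat <- data.frame(name = c("a", "b"), size = c(100L, 90L),
                    frac_R = c(1, 1), frac_E = c(1, 1))
  ut <- generate_utilization(sim_truth(seed = 1, classes = sat))
  expect_true(all(ut$util == 1L))
  expect_equal(ncol(ut$util), 190L)
  expect_equal(as.integer(table(ut$classes)[c("a", "b")]), c(100L, 90L))

  expect_error(sim_truth(seed = 1,
                         classes = data.frame(name = "a", size = 190L,
                                              frac_R = 1.2, frac_E = 0.5)),
               "fractions")
  # default profile: 190 compounds across 9 classes
  ut9 <- generate_utilization(sim_truth(seed = 2))
  expect_equal(ncol(ut9$util), 190L)
  expect_equal(length(unique(unname(ut9$classes))), 9L)
  expect_equal(nrow(ut9$util), 19L)
})

test_that("prediction noise maps onto validation accuracy", {
  set.seed(44)
  obs <- random_presence(10, 50)
  expect_equal(
    suppressMessages(validate_predictions(
      generate_predictions(obs, 0, seed = 1), obs))$overall_accuracy, 100)
  expect_equal(
    suppressMessages(validate_predictions(
      generate_predictions(obs, 1, seed = 1), obs))$overall_accuracy, 0)
})

test_that("alignment generator matches its mutation rate", {
  cons <- random_sequence(1500, seed = 12)
  ident <- generate_alignment(cons, n = 4, mu = 0, seed = 5)
  expect_true(all(unclass(ident) == cons))
  expect_equal(consensus_similarity(ident)$similarity, rep(100, 4))

  aln <- generate_alignment(cons, n = 19, mu = 0.01, seed = 6)
  sims <- consensus_similarity(aln)$similarity
  expect_equal(mean(sims), 99.0, tolerance = 0.002) # +/- 0.2 on 99.0
})

test_that("trait generator respects prevalences", {
  tr <- data.frame(name = c("aligned", "absent"), prev_R = c(0, 0),
                   prev_E = c(1, 0))
  m <- generate_traits(sim_truth(seed = 9, traits = tr))
  lab <- make_labels(4, 15)
  expect_equal(unname(m[, "aligned"]),
               c(rep(0L, 4), rep(1L, 15)))
  expect_true(all(m[, "absent"] == 0L))
})

test_that("bundles are complete, loadable and seeded", {
  dir <- tempfile()
  paths <- generate_bundle(small_truth(seed = 21), dir)
  expect_true(all(file.exists(unlist(paths))))
  truth_json <- jsonlite::read_json(paths$truth)
  expect_equal(truth_json$seed, 21L)
  cs <- read_ortholog_groups(paths$groups)
  expect_equal(length(cs), 40L)
  util <- read_presence_matrix(paths$utilization, kind = "utilization")
  classes <- read_compound_classes(paths$classes)
  expect_setequal(colnames(util), names(classes))
  aln <- read_alignment(paths$alignment)
  expect_length(aln, 19)
})
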