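test_that("trait tables tabulate compartment by outcome", {
  lab <- make_labels(4, 15)
  y <- integer(19)
  y[c(1, 5:12)] <- 1L # 1 of 4 rhizosphere, 8 of 15 endosphere positive
  m <- make_matrix(matrix(y, ncol = 1), strains = names(lab),
                   features = "phosphate")
  tab <- build_trait_table(m, lab, "phosphate")
  expect_equal(unname(tab), matrix(c(1L, 8L, 3L, 7L), 2))
  expect_error(build_trait_table(m, lab, "nope"), "unknown trait")

  all_pos <- make_matrix(matrix(1L, 19, 1), strains = names(lab),
                         features = "t")
  expect_equal(unname(build_trait_table(all_pos, lab, "t")[, "negative"]),
               c(0L, 0L))
})

test_that("Pearson chi-square matches hand values and the stats oracle", {
  homog <- matrix(c(5, 5, 5, 5), 2)
  r <- chi_square_hushed(homog)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_asymptotic, 1)

  perfect <- matrix(c(10, 0, 0, 10), 2)
  r2 <- chi_square_hushed(perfect)
  expect_equal(r2$chi2, 20.0)
  expect_equal(r2$df, 1L)

  set.seed(11)
  for (rep in 1:50) {
    nr <- 2; nc <- sample(2:5, 1)
    tab <- matrix(rpois(nr * nc, 8) + 1, nr, nc)
    mine <- chi_square_hushed(tab)
    expect_equal(mine$chi2, oracle_chi2(tab), tolerance = 1e-12)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_asymptotic, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(as.integer(ref$parameter)))
    # invariant under swapping the compartment rows
    expect_equal(chi_square_hushed(tab[2:1, ])$chi2, mine$chi2)
  }
})

test_that("chi-square rejects degenerate tables and flags small cells", {
  expect_error(chi_square_hushed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(chi_square_hushed(matrix(c(0, 3, 0, 4), 2)), "margin")
  expect_error(chi_square_hushed(matrix(c(1, 2, 3), 3, 1)), "2x2")
  expect_warning(chi_square(matrix(c(1, 3, 2, 4), 2)),
                 class = "rhizendo_small_expected")
})

test_that("permutation p matches exhaustive enumeration on small designs", {
  # 2 + 2 strains, trait = compartment indicator: exact p = 1/3
  lab <- make_labels(2, 2)
  y <- c(1L, 1L, 0L, 0L)
  m <- make_matrix(matrix(y, ncol = 1), strains = names(lab), features = "t")
  expect_equal(oracle_perm_p(y, unclass(lab)), 1 / 3)
  res <- permutation_chi_square(m, lab, "t", n_perm = 4999, seed = 8)
  expect_equal(res$p_permutation, 1 / 3, tolerance = 0.1)
  expect_equal(res$direction, "rhizosphere")

  # a 3 + 4 design against full enumeration
  lab2 <- make_labels(3, 4)
  set.seed(21)
  for (rep in 1:5) {
    y2 <- rbinom(7, 1, 0.5)
    if (sum(y2) %in% c(0, 7)) next
    m2 <- make_matrix(matrix(y2, ncol = 1), strains = names(lab2),
                      features = "t")
    exact <- oracle_perm_p(y2, unclass(lab2))
    est <- permutation_chi_square(m2, lab2, "t", n_perm = 4999,
                                  seed = 30 + rep)$p_permutation
    expect_equal(est, exact, tolerance = 0.05)
  }
})

test_that("permutation p is seeded and near 1 for homogeneous traits", {
  lab <- make_labels(4, 15)
  set.seed(3)
  y <- rbinom(19, 1, 0.5)
  m <- make_matrix(matrix(y, ncol = 1), strains = names(lab), features = "t")
  a <- permutation_chi_square(m, lab, "t", n_perm = 500, seed = 42)
  b <- permutation_chi_square(m, lab, "t", n_perm = 500, seed = 42)
  expect_identical(a$p_permutation, b$p_permutation)

  # perfectly homogeneous fractions: every permuted table is at least as
  # extreme, so p is 1
  lab22 <- make_labels(2, 2)
  mh <- make_matrix(matrix(c(1L, 0L, 1L, 0L), ncol = 1),
                    strains = names(lab22), features = "t")
  ph <- permutation_chi_square(mh, lab22, "t", n_perm = 300,
                               seed = 1)$p_permutation
  expect_gt(ph, 0.95)
})

test_that("stacked multivariate table behaves like one big chi-square", {
  lab <- make_labels(2, 2)
  # identical compartment fractions for both traits -> chi2 = 0
  m <- make_matrix(rbind(c(1, 1), c(0, 0), c(1, 1), c(0, 0)),
                   strains = names(lab), features = c("tA", "tB"))
  res <- suppressWarnings(multivariate_enrichment(m, lab, alpha = 0.05))
  expect_equal(res$overall$chi2, 0)

  # K perfectly compartment-aligned traits (two per direction) clear the
  # critical value: stacked positives are all-R for t1/t2, all-E for t3/t4
  lab2 <- make_labels(5, 5)
  K <- 4
  m2 <- make_matrix(cbind(rbind(matrix(1L, 5, 2), matrix(0L, 5, 2)),
                          rbind(matrix(0L, 5, 2), matrix(1L, 5, 2))),
                    strains = names(lab2),
                    features = paste0("t", 1:K))
  res2 <- suppressWarnings(multivariate_enrichment(m2, lab2))
  expect_gt(res2$overall$chi2, stats::qchisq(0.95, df = K - 1))
  expect_equal(res2$overall$chi2, oracle_chi2(res2$table), tolerance = 1e-12)
  expect_length(res2$per_trait, K)
  # direction reflects the higher mean positive fraction
  m3 <- m2; m3[, 4] <- 0L; m3[1, 4] <- 1L
  res3 <- suppressWarnings(multivariate_enrichment(m3, lab2))
  expect_equal(res3$overall$direction, "rhizosphere")

  expect_error(multivariate_enrichment(m2, lab2, trait_ids = "t1"),
               "at least 2")
})

test_that("trait panels report per-trait rows with degenerate traits as NA", {
  lab <- make_labels(4, 15)
  set.seed(14)
  m <- cbind(random_presence(19, 3), all_pos = rep(1L, 19))
  rownames(m) <- names(lab)
  out <- enrich_traits(m, lab, alpha = 0.05, n_perm = 99, seed = 5)
  expect_equal(nrow(out), 4)
  expect_true(is.na(out$chi2[out$trait_id == "all_pos"]))
  expect_true(all(!is.na(out$p_permutation[out$trait_id != "all_pos"])))
  # BH adjustment adds a column and keeps p ordering
  out_bh <- enrich_traits(m, lab, alpha = 0.05, n_perm = 0, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(out_bh))
  expect_true(all(out_bh$p_adjusted >= out_bh$p_asymptotic, na.rm = TRUE))
})

test_that("planted compartment-aligned traits are detected with power", {
  # light power check (full-scale version in the acceptance suite)
  lab <- make_labels(4, 15)
  set.seed(8)
  hits <- 0; n_sim <- 30
  for (s in 1:n_sim) {
    y <- c(rep(0L, 4), rbinom(15, 1, 0.8))
    if (sum(y) == 0) next
    m <- make_matrix(matrix(y, ncol = 1), strains = names(lab),
                     features = "t")
    p <- permutation_chi_square(m, lab, "t", n_perm = 199,
                                seed = s)$p_permutation
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.7)
})
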