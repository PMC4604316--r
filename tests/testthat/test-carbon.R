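test_that("per-strain substrate counts are row sums with group ranges", {
  lab <- make_labels(2, 3)
  m <- make_matrix(rbind(c(0, 0, 0), c(1, 1, 1), c(1, 0, 0),
                         c(1, 1, 0), c(0, 1, 1)), strains = names(lab))
  out <- strain_substrate_counts(m, lab)
  expect_equal(out$n_utilized, c(0L, 3L, 1L, 2L, 2L))
  rng <- attr(out, "group_range")
  expect_equal(rng$min[rng$compartment == "rhizosphere"], 0L)
  expect_equal(rng$max[rng$compartment == "rhizosphere"], 3L)
  expect_equal(rng$min[rng$compartment == "endosphere"], 1L)

  set.seed(2)
  r <- random_presence(10, 40)
  expect_equal(strain_substrate_counts(r)$n_utilized,
               unname(apply(r, 1, sum)))
})

test_that("all/none/differential partitions the compound set", {
  ones <- make_matrix(matrix(1L, 4, 7))
  gp <- group_partition(ones)
  expect_equal(c(gp$n_all, gp$n_none, gp$n_differential), c(7L, 0L, 0L))

  set.seed(9)
  for (rep in 1:15) {
    m <- random_presence(6, sample(10:60, 1))
    sub <- sample(rownames(m), sample(1:6, 1))
    gp <- group_partition(m, sub)
    expect_equal(gp$n_all + gp$n_none + gp$n_differential, ncol(m))
    # oracle: direct column scans over the subset
    s <- m[sub, , drop = FALSE]
    expect_equal(gp$n_all, sum(apply(s, 2, function(v) all(v == 1))))
    expect_equal(gp$n_none, sum(apply(s, 2, function(v) all(v == 0))))
  }
  expect_error(group_partition(ones, character(0)), "non-empty")
  expect_error(group_partition(ones, "nope"), "not in matrix")
})

test_that("class bias calls follow the pooled chi-square and fractions", {
  lab <- make_labels(2, 2)
  classes <- stats::setNames(rep(c("balanced", "endo"), each = 10),
                             sprintf("f%02d", 1:20))
  # balanced class: every strain uses exactly half its compounds
  bal <- cbind(matrix(rep(c(1L, 0L), each = 5), 4, 10, byrow = TRUE))
  # endosphere class: all E positive, all R negative
  endo <- rbind(matrix(0L, 2, 10), matrix(1L, 2, 10))
  m <- make_matrix(cbind(bal, endo), strains = names(lab),
                   features = names(classes))
  out <- classify_group_bias(m, lab, classes, alpha = 0.01)
  bal_row <- out[out$class == "balanced", ]
  expect_equal(bal_row$chi2, 0)
  expect_equal(bal_row$bias_call, "none")
  expect_equal(bal_row$frac_R, bal_row$frac_E)
  endo_row <- out[out$class == "endo", ]
  expect_equal(endo_row$bias_call, "endosphere")
  # hand value: pooled table [[0,20],[20,0]] -> chi2 = 40
  expect_equal(endo_row$chi2, 40)

  expect_error(classify_group_bias(m, lab, classes[-1], alpha = 0.01),
               "without a class")
  classes_extra <- c(classes, ghost = "empty_class")
  expect_error(classify_group_bias(m, lab, classes_extra, alpha = 0.01),
               "zero compounds")
})

test_that("class bias is invariant to strain and compound order", {
  set.seed(30)
  lab <- make_labels(4, 6)
  m <- random_presence(10, 30)
  rownames(m) <- names(lab)
  classes <- stats::setNames(sample(rep(c("a", "b", "c"), each = 10)),
                             colnames(m))
  base <- classify_group_bias(m, lab, classes, alpha = 0.05)
  perm <- classify_group_bias(m[sample(10), sample(30)], lab, classes,
                              alpha = 0.05)
  base <- base[order(base$class), ]; perm <- perm[order(perm$class), ]
  rownames(base) <- rownames(perm) <- NULL
  expect_equal(base, perm)
})

test_that("planted class bias is recovered across seeds", {
  # light recovery check at planted delta = 0.5 (full scale in acceptance)
  cl <- data.frame(name = c("target", "background"), size = c(20L, 170L),
                   frac_R = c(0.7, 0.45), frac_E = c(0.2, 0.45))
  hits <- 0
  for (s in 1:30) {
    ut <- generate_utilization(sim_truth(seed = s, classes = cl))
    gb <- classify_group_bias(ut$util, ut$labels, ut$classes, alpha = 0.01)
    if (gb$bias_call[gb$class == "target"] == "rhizosphere") hits <- hits + 1
  }
  expect_gt(hits / 30, 0.9)
})

test_that("top-biased compounds rank by fraction difference", {
  lab <- make_labels(2, 2)
  m <- make_matrix(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 0), c(0, 1, 1)),
                   strains = names(lab), features = c("cA", "cB", "cC"))
  top <- top_biased_compounds(m, lab, k = 3, direction = "rhizosphere")
  expect_equal(top$compound_id[1], "cA")   # R-exclusive, score +1
  expect_equal(top$score[1], 1.0)
  expect_equal(top$score[top$compound_id == "cB"], 0.0) # uniform
  expect_equal(top$score[top$compound_id == "cC"], -0.5)

  expect_error(top_biased_compounds(m, lab, k = 4), "exceeds")
  expect_error(top_biased_compounds(m, lab, k = 0), ">= 1")

  # oracle: brute-force score sort with lexicographic ties
  set.seed(17)
  for (rep in 1:10) {
    r <- random_presence(6, 25)
    lab6 <- make_labels(3, 3)
    rownames(r) <- names(lab6)
    mine <- top_biased_compounds(r, lab6, k = 25, direction = "endosphere")
    fr <- colMeans(r[1:3, , drop = FALSE])
    fe <- colMeans(r[4:6, , drop = FALSE])
    sc <- fe - fr
    ord <- order(-sc, colnames(r))
    expect_equal(mine$compound_id, colnames(r)[ord])
    expect_equal(mine$score, unname(sc[ord]))
  }
})
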