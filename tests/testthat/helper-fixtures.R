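# Fixture builders and independent oracles shared across the suite.

# binary matrix with generated ids
make_matrix <- function(values, strains = NULL, features = NULL) {
  m <- as.matrix(values)
  rownames(m) <- strains %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- features %||% sprintf("f%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_labels <- function(n_R, n_E) {
  compartment_labels(stats::setNames(
    c(rep("rhizosphere", n_R), rep("endosphere", n_E)),
    c(sprintf("R%02d", seq_len(n_R)), sprintf("E%02d", seq_len(n_E)))))
}

# random binary matrix guaranteed to have no all-zero feature column
random_presence <- function(n_strains, n_features, p = 0.5) {
  m <- matrix(rbinom(n_strains * n_features, 1L, p), n_strains)
  empty <- colSums(m) == 0L
  for (j in which(empty)) m[sample.int(n_strains, 1L), j] <- 1L
  make_matrix(m)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

chi_square_hushed <- function(tab, ...) suppressWarnings(chi_square(tab, ...))

# --- independent oracles -----------------------------------------------------

# brute-force per-feature occupancy classifier (set logic, no shared code)
oracle_venn_counts <- function(m, labels) {
  lab <- unclass(labels)[rownames(m)]
  r <- rownames(m)[lab == "rhizosphere"]
  e <- rownames(m)[lab == "endosphere"]
  occ <- function(col, grp) {
    present <- rownames(m)[m[, col] == 1L]
    inside <- intersect(present, grp)
    if (length(inside) == length(grp)) "all"
    else if (length(inside) == 0L) "none"
    else "some"
  }
  counts <- matrix(0L, 3, 3, dimnames = list(c("all", "some", "none"),
                                             c("all", "some", "none")))
  for (j in colnames(m)) {
    counts[occ(j, r), occ(j, e)] <- counts[occ(j, r), occ(j, e)] + 1L
  }
  counts
}

# brute-force Pearson chi-square by summing cells
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    total <- total + (tab[i, j] - e)^2 / e
  }
  total
}

# exhaustive label-permutation p-value for one binary trait
oracle_perm_p <- function(y, lab) {
  n <- length(y)
  n_r <- sum(lab == "rhizosphere")
  chi2_for <- function(r_idx) {
    r <- seq_len(n) %in% r_idx
    tab <- matrix(c(sum(y[r]), sum(y[!r]),
                    sum(r) - sum(y[r]), sum(!r) - sum(y[!r])), 2)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  }
  obs <- chi2_for(which(lab == "rhizosphere"))
  combos <- utils::combn(n, n_r)
  stats_all <- apply(combos, 2, chi2_for)
  mean(stats_all >= obs - 1e-12)
}
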