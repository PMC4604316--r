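# Contingency chi-square machinery for compartment bias testing.
#
# The statistic is the plain Pearson chi-square with no continuity correction.
# With 4-vs-15 group sizes expected cells are routinely < 5, so the asymptotic
# p-value is advisory; the label-permutation p-value is the recommended
# small-sample result and a warning condition flags small expected counts.

# run expr with a temporary RNG state seeded from `seed`; global stream
# untouched. seed = NULL runs with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

new_enrichment_result <- function(chi2, df, p_asymptotic, min_expected, alpha,
                                  p_permutation = NA_real_,
                                  direction = NA_character_) {
  p_use <- if (!is.na(p_permutation)) p_permutation else p_asymptotic
  structure(list(chi2 = chi2, df = df,
                 p_asymptotic = p_asymptotic,
                 p_permutation = p_permutation,
                 min_expected = min_expected,
                 alpha = alpha,
                 verdict = p_use <= alpha,
                 direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("chi2 = %.4g (df = %d), p_asymptotic = %.4g", x$chi2, x$df,
              x$p_asymptotic))
  if (!is.na(x$p_permutation))
    cat(sprintf(", p_permutation = %.4g", x$p_permutation))
  cat(sprintf("\nmin expected cell = %.3g; %s at alpha = %g",
              x$min_expected,
              if (isTRUE(x$verdict)) "SIGNIFICANT" else "not significant",
              x$alpha))
  if (!is.na(x$direction)) cat("; direction:", x$direction)
  cat("\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Computes `sum((obs - exp)^2 / exp)` with expectations from the row/column
#' margins, df = (rows-1)(cols-1), and the asymptotic p-value from the
#' chi-square distribution. No continuity correction is applied. A zero row
#' or column margin collapses the degrees of freedom and is an error; a
#' smallest expected cell below 5 raises a warning of class
#' `rhizendo_small_expected` (the asymptotic approximation is then dubious and
#' a permutation p-value should be preferred).
#'
#' @param table non-negative integer matrix (rows = compartments, columns =
#'   outcome categories), at least 2x2 in shape and grand total >= 1.
#' @param alpha significance level for the verdict field (default 0.05).
#' @return an `enrichment_result` (fields `chi2`, `df`, `p_asymptotic`,
#'   `p_permutation` = NA, `min_expected`, `verdict`, `direction` = NA).
#' @export
chi_square <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (anyNA(table) || any(table < 0))
    stop("contingency table must be non-negative with no missing cells")
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2x2")
  n <- sum(table)
  if (n < 1) stop("contingency table grand total must be >= 1")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stop("zero row margin for: ",
         paste(if (is.null(rownames(table))) which(rs == 0) else
               rownames(table)[rs == 0], collapse = ", "))
  if (any(cs == 0))
    stop("zero column margin for: ",
         paste(if (is.null(colnames(table))) which(cs == 0) else
               colnames(table)[cs == 0], collapse = ", "))
  expected <- outer(rs, cs) / n
  chi2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  if (min(expected) < 5)
    warning(warningCondition(
      sprintf("smallest expected cell is %.3g (< 5); asymptotic p-value unreliable, prefer the permutation test",
              min(expected)),
      class = "rhizendo_small_expected"))
  new_enrichment_result(chi2 = chi2, df = df,
                        p_asymptotic = stats::pchisq(chi2, df, lower.tail = FALSE),
                        min_expected = min(expected), alpha = alpha)
}

#' Compartment-by-trait 2x2 table for one trait
#'
#' @param traits a [presence_matrix()] of binary traits (strains x traits).
#' @param labels a [compartment_labels()] covering every strain.
#' @param trait_id trait (column) to tabulate.
#' @return 2x2 integer matrix, rows `rhizosphere`/`endosphere`, columns
#'   `positive`/`negative`.
#' @export
build_trait_table <- function(traits, labels, trait_id) {
  traits <- as_presence(traits, "traits")
  if (!trait_id %in% colnames(traits))
    stop("unknown trait: ", trait_id)
  lab <- check_labels(labels, rownames(traits))
  y <- traits[, trait_id]
  pos <- c(rhizosphere = sum(y[lab == "rhizosphere"]),
           endosphere = sum(y[lab == "endosphere"]))
  tot <- c(rhizosphere = sum(lab == "rhizosphere"),
           endosphere = sum(lab == "endosphere"))
  matrix(as.integer(c(pos, tot - pos)), nrow = 2,
         dimnames = list(compartment = c("rhizosphere", "endosphere"),
                         outcome = c("positive", "negative")))
}

# Shared label-permutation engine. Each strain i contributes pos[i] positive
# calls out of tot[i]; a permutation re-draws which strains form the
# rhizosphere group (sizes preserved) and rebuilds the pooled 2x2 table. The
# chi-square of a 2x2 with fixed margins is a function of the rhizosphere
# positive count alone, so the permuted statistics vectorize.
perm_chi2_pooled <- function(pos, tot, lab, n_perm, seed = NULL) {
  n <- length(pos)
  n_r <- sum(lab == "rhizosphere")
  obs <- pooled_table(pos, tot, lab)
  res <- chi_square_quiet(obs)
  P <- sum(pos); Tt <- sum(tot)
  tot_r_obs <- sum(tot[lab == "rhizosphere"])
  chi2_from_k <- function(k, tot_r) {
    o <- cbind(k, tot_r - k, P - k, (Tt - tot_r) - (P - k))
    e <- cbind(P * tot_r / Tt, (Tt - P) * tot_r / Tt,
               P * (Tt - tot_r) / Tt, (Tt - P) * (Tt - tot_r) / Tt)
    rowSums((o - e)^2 / e)
  }
  perm_stat <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n, n_r))
    idx <- matrix(idx, nrow = n_r)
    k <- colSums(matrix(pos[idx], nrow = n_r))
    tot_r <- colSums(matrix(tot[idx], nrow = n_r))
    chi2_from_k(k, tot_r)
  })
  p_perm <- (1 + sum(perm_stat >= res$chi2 - 1e-12)) / (n_perm + 1)
  list(observed = res, p_permutation = p_perm, table = obs)
}

pooled_table <- function(pos, tot, lab) {
  r <- lab == "rhizosphere"
  matrix(as.integer(c(sum(pos[r]), sum(pos[!r]),
                      sum(tot[r]) - sum(pos[r]), sum(tot[!r]) - sum(pos[!r]))),
         nrow = 2,
         dimnames = list(compartment = c("rhizosphere", "endosphere"),
                         outcome = c("positive", "negative")))
}

chi_square_quiet <- function(table, alpha = 0.05)
  withCallingHandlers(chi_square(table, alpha),
                      rhizendo_small_expected = function(w)
                        invokeRestart("muffleWarning"))

#' Label-permutation chi-square test for one trait
#'
#' Compares the observed 2x2 chi-square with its distribution under random
#' reassignment of strains to compartments (group sizes preserved). The
#' permutation p-value uses the add-one estimator
#' `(1 + #permutations with chi2 >= observed) / (n_perm + 1)` and is exactly
#' reproducible for a given seed.
#'
#' @inheritParams build_trait_table
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param alpha significance level for the verdict.
#' @return an `enrichment_result` with `p_permutation` filled in and
#'   `direction` the compartment with the higher positive fraction (NA when
#'   the fractions tie).
#' @export
permutation_chi_square <- function(traits, labels, trait_id, n_perm = 1000,
                                   seed = NULL, alpha = 0.05) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  traits <- as_presence(traits, "traits")
  if (!trait_id %in% colnames(traits)) stop("unknown trait: ", trait_id)
  lab <- check_labels(labels, rownames(traits))
  y <- traits[, trait_id]
  pr <- perm_chi2_pooled(y, rep(1L, length(y)), lab, n_perm, seed)
  res <- pr$observed
  res$p_permutation <- pr$p_permutation
  res$direction <- table_direction(pr$table)
  res$alpha <- alpha
  res$verdict <- pr$p_permutation <= alpha
  res
}

# compartment with the higher positive fraction of a pooled 2x2, NA on tie
table_direction <- function(tab) {
  fr <- tab[, "positive"] / rowSums(tab)
  if (fr[1] == fr[2]) NA_character_ else rownames(tab)[which.max(fr)]
}

#' Multivariate (stacked) compartment enrichment over several traits
#'
#' Builds a 2xK table of per-compartment positive counts across K traits and
#' tests it for non-homogeneity with the Pearson chi-square; per-trait 2x2
#' results are returned alongside. This stacked construction treats the K
#' traits as the columns of one contingency table, which is one defensible
#' reading of "multivariate contingency chi-square" over a trait panel.
#'
#' @inheritParams build_trait_table
#' @param trait_ids traits to include (default: all columns); at least 2.
#' @param alpha significance level.
#' @param n_perm if > 0, also compute a label-permutation p-value for the
#'   stacked statistic with `n_perm` permutations.
#' @param seed seed for the permutation stream.
#' @return list with `overall` (an `enrichment_result` for the stacked 2xK
#'   table), `table` (the 2xK matrix) and `per_trait` (named list of 2x2
#'   `enrichment_result`s).
#' @export
multivariate_enrichment <- function(traits, labels, trait_ids = NULL,
                                    alpha = 0.05, n_perm = 0, seed = NULL) {
  traits <- as_presence(traits, "traits")
  if (is.null(trait_ids)) trait_ids <- colnames(traits)
  if (length(trait_ids) < 2L)
    stop("multivariate enrichment needs at least 2 traits")
  missing <- setdiff(trait_ids, colnames(traits))
  if (length(missing)) stop("unknown trait(s): ", paste(missing, collapse = ", "))
  lab <- check_labels(labels, rownames(traits))
  r <- lab == "rhizosphere"
  sub <- traits[, trait_ids, drop = FALSE]
  stacked <- rbind(rhizosphere = colSums(sub[r, , drop = FALSE]),
                   endosphere = colSums(sub[!r, , drop = FALSE]))
  overall <- chi_square(stacked, alpha = alpha)
  fr_r <- mean(sub[r, , drop = FALSE]); fr_e <- mean(sub[!r, , drop = FALSE])
  overall$direction <- if (fr_r == fr_e) NA_character_ else
    c("rhizosphere", "endosphere")[which.max(c(fr_r, fr_e))]
  if (n_perm > 0) {
    obs_chi2 <- overall$chi2
    n_r <- sum(r)
    perm_stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      pr <- seq_len(nrow(sub)) %in% sample.int(nrow(sub), n_r)
      st <- rbind(colSums(sub[pr, , drop = FALSE]),
                  colSums(sub[!pr, , drop = FALSE]))
      if (any(colSums(st) == 0) || any(rowSums(st) == 0)) return(0)
      e <- outer(rowSums(st), colSums(st)) / sum(st)
      sum((st - e)^2 / e)
    }, numeric(1)))
    overall$p_permutation <- (1 + sum(perm_stat >= obs_chi2 - 1e-12)) / (n_perm + 1)
    overall$verdict <- overall$p_permutation <= alpha
  }
  per_trait <- lapply(trait_ids, function(tid) {
    tab <- build_trait_table(traits, labels, tid)
    res <- try(chi_square_quiet(tab, alpha = alpha), silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    res$direction <- table_direction(tab)
    res
  })
  names(per_trait) <- trait_ids
  list(overall = overall, table = stacked, per_trait = per_trait)
}

#' Per-trait compartment enrichment table
#'
#' Runs the 2x2 chi-square (and optionally the permutation test) for every
#' trait column and assembles the flat results table written by the pipeline.
#' Traits with a degenerate margin (all strains positive, or all negative)
#' carry NA statistics rather than aborting the whole panel.
#'
#' @inheritParams build_trait_table
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per trait (0 disables the permutation column).
#' @param seed integer seed for the permutation stream.
#' @param p_adjust `"none"` (default) or `"BH"` to add Benjamini-Hochberg
#'   adjusted p-values across traits (adjusting the permutation p when
#'   available, otherwise the asymptotic one).
#' @return data frame with columns `trait_id`, `chi2`, `df`, `p_asymptotic`,
#'   `p_permutation`, `min_expected`, `direction`, `verdict` (and `p_adjusted`
#'   when requested).
#' @export
enrich_traits <- function(traits, labels, alpha = 0.05, n_perm = 0,
                          seed = NULL, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  traits <- as_presence(traits, "traits")
  lab <- check_labels(labels, rownames(traits))
  ids <- colnames(traits)
  seeds <- if (is.null(seed)) rep(list(NULL), length(ids)) else
    as.list(seed + seq_along(ids) - 1L)
  rows <- lapply(seq_along(ids), function(i) {
    tid <- ids[i]
    tab <- build_trait_table(traits, labels, tid)
    base <- data.frame(trait_id = tid, chi2 = NA_real_, df = NA_integer_,
                       p_asymptotic = NA_real_, p_permutation = NA_real_,
                       min_expected = NA_real_, direction = NA_character_,
                       verdict = NA, stringsAsFactors = FALSE)
    res <- try(chi_square_quiet(tab, alpha = alpha), silent = TRUE)
    if (inherits(res, "try-error")) return(base)
    if (n_perm > 0)
      res <- permutation_chi_square(traits, labels, tid, n_perm = n_perm,
                                    seed = seeds[[i]], alpha = alpha)
    base$chi2 <- res$chi2; base$df <- res$df
    base$p_asymptotic <- res$p_asymptotic
    base$p_permutation <- res$p_permutation
    base$min_expected <- res$min_expected
    base$direction <- if (is.null(res$direction) || is.na(res$direction))
      table_direction(tab) else res$direction
    base$verdict <- res$verdict
    base
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    p <- ifelse(is.na(out$p_permutation), out$p_asymptotic, out$p_permutation)
    out$p_adjusted <- stats::p.adjust(p, method = "BH")
    out$verdict <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  }
  rownames(out) <- NULL
  out
}
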