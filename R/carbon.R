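#' Per-strain substrate utilization counts
#'
#' Counts the carbon sources each strain oxidizes (row sums of the binary
#' utilization matrix). When compartment labels are supplied the result also
#' carries the per-compartment min/max range as a `"group_range"` attribute.
#'
#' @param util a [presence_matrix()] of utilization calls (strains x
#'   compounds).
#' @param labels optional [compartment_labels()].
#' @return data frame with `strain_id`, `n_utilized` (and `compartment` when
#'   labelled); attribute `group_range` is a data frame of per-compartment
#'   min/max counts.
#' @export
strain_substrate_counts <- function(util, labels = NULL) {
  util <- as_presence(util, "util")
  out <- data.frame(strain_id = rownames(util),
                    n_utilized = as.integer(rowSums(util)),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lab <- check_labels(labels, rownames(util))
    out$compartment <- unname(lab)
    rng <- do.call(rbind, lapply(split(out$n_utilized, out$compartment),
                                 function(v) data.frame(min = min(v), max = max(v))))
    attr(out, "group_range") <- data.frame(compartment = rownames(rng), rng,
                                           row.names = NULL)
  }
  out
}

#' All/none/differential partition of compounds within a strain group
#'
#' Within the given strain subset each compound is used by every strain
#' (`all`), by none (`none`), or differentially (`differential`); the three
#' counts always partition the compound set.
#'
#' @param util a [presence_matrix()] (strains x compounds).
#' @param strains strain subset to evaluate (default: every strain).
#' @return list with counts `n_all`, `n_none`, `n_differential` and the
#'   corresponding compound id vectors `all`, `none`, `differential`.
#' @export
group_partition <- function(util, strains = rownames(util)) {
  util <- as_presence(util, "util")
  strains <- as.character(strains)
  if (length(strains) == 0L) stop("strain subset must be non-empty")
  missing <- setdiff(strains, rownames(util))
  if (length(missing))
    stop("strain(s) not in matrix: ", paste(missing, collapse = ", "))
  s <- colSums(util[strains, , drop = FALSE])
  cls <- ifelse(s == length(strains), "all", ifelse(s == 0L, "none", "differential"))
  list(n_all = sum(cls == "all"),
       n_none = sum(cls == "none"),
       n_differential = sum(cls == "differential"),
       all = colnames(util)[cls == "all"],
       none = colnames(util)[cls == "none"],
       differential = colnames(util)[cls == "differential"])
}

#' Compartment bias of compound classes
#'
#' For each compound class, pools all strain-by-compound calls into one 2x2
#' table (compartment x positive/negative), tests it for non-homogeneity with
#' the Pearson chi-square (optionally a strain-label permutation test), and —
#' when significant at `alpha` — calls the bias toward the compartment with
#' the larger pooled utilization fraction.
#'
#' Pooling treats strain-compound calls within a class as exchangeable, which
#' overstates the effective sample size when strains differ systematically;
#' the permutation test (which permutes strain labels, keeping each strain's
#' calls intact) is the robust alternative and is preferred for the verdict
#' when computed.
#'
#' @param util a [presence_matrix()] (strains x compounds).
#' @param labels a [compartment_labels()].
#' @param classes named character vector mapping every compound id in `util`
#'   to a class name (see [read_compound_classes()]).
#' @param alpha significance level for the bias call (default 0.01).
#' @param n_perm strain-label permutations per class (0 disables).
#' @param seed integer seed for the permutation stream.
#' @return data frame, one row per class: `class`, `n_compounds`, `frac_R`,
#'   `frac_E`, `chi2`, `df`, `p_asymptotic`, `p_permutation`, `min_expected`,
#'   `bias_call` (`rhizosphere`/`endosphere`/`none`).
#' @export
classify_group_bias <- function(util, labels, classes, alpha = 0.01,
                                n_perm = 0, seed = NULL) {
  util <- as_presence(util, "util")
  lab <- check_labels(labels, rownames(util))
  unclassified <- setdiff(colnames(util), names(classes))
  if (length(unclassified))
    stop("compound(s) without a class: ", paste(unclassified, collapse = ", "))
  class_of <- classes[colnames(util)]
  class_names <- unique(unname(classes))
  empty <- setdiff(class_names, unique(unname(class_of)))
  if (length(empty))
    stop("class(es) with zero compounds in the matrix: ",
         paste(empty, collapse = ", "))
  class_names <- unique(unname(class_of)) # matrix order
  seeds <- if (is.null(seed)) rep(list(NULL), length(class_names)) else
    as.list(seed + seq_along(class_names) - 1L)
  r <- lab == "rhizosphere"
  rows <- lapply(seq_along(class_names), function(ci) {
    cl <- class_names[ci]
    cols <- colnames(util)[class_of == cl]
    sub <- util[, cols, drop = FALSE]
    pos <- rowSums(sub)
    tot <- rep(length(cols), nrow(sub))
    tab <- pooled_table(pos, tot, lab)
    frac <- tab[, "positive"] / rowSums(tab)
    res <- try(chi_square_quiet(tab, alpha = alpha), silent = TRUE)
    if (inherits(res, "try-error")) {
      # degenerate margin: every call positive (or negative) in both groups
      return(data.frame(class = cl, n_compounds = length(cols),
                        frac_R = frac[["rhizosphere"]],
                        frac_E = frac[["endosphere"]],
                        chi2 = NA_real_, df = NA_integer_,
                        p_asymptotic = NA_real_, p_permutation = NA_real_,
                        min_expected = NA_real_, bias_call = "none",
                        stringsAsFactors = FALSE))
    }
    p_perm <- NA_real_
    if (n_perm > 0) {
      pr <- perm_chi2_pooled(pos, tot, lab, n_perm, seeds[[ci]])
      p_perm <- pr$p_permutation
    }
    p_use <- if (!is.na(p_perm)) p_perm else res$p_asymptotic
    call <- if (p_use <= alpha && frac[1] != frac[2])
      names(frac)[which.max(frac)] else "none"
    data.frame(class = cl, n_compounds = length(cols),
               frac_R = frac[["rhizosphere"]], frac_E = frac[["endosphere"]],
               chi2 = res$chi2, df = res$df,
               p_asymptotic = res$p_asymptotic, p_permutation = p_perm,
               min_expected = res$min_expected, bias_call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top compartment-biased compounds
#'
#' Scores every compound as the difference between the utilization fraction
#' of the target compartment and the other compartment, sorts descending and
#' returns the top `k`; ties break lexicographically on compound id so the
#' ranking is deterministic.
#'
#' @param util a [presence_matrix()] (strains x compounds).
#' @param labels a [compartment_labels()].
#' @param k number of compounds to return (1 <= k <= number of compounds).
#' @param direction `"rhizosphere"` or `"endosphere"`.
#' @return data frame with `compound_id`, `frac_R`, `frac_E`, `score`
#'   (fraction difference toward `direction`), best first.
#' @export
top_biased_compounds <- function(util, labels, k,
                                 direction = c("rhizosphere", "endosphere")) {
  direction <- match.arg(direction)
  util <- as_presence(util, "util")
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(util))
    stop("k (", k, ") exceeds the number of compounds (", ncol(util), ")")
  lab <- check_labels(labels, rownames(util))
  r <- lab == "rhizosphere"
  frac_R <- colMeans(util[r, , drop = FALSE])
  frac_E <- colMeans(util[!r, , drop = FALSE])
  score <- if (direction == "rhizosphere") frac_R - frac_E else frac_E - frac_R
  ord <- order(-score, colnames(util))
  out <- data.frame(compound_id = colnames(util)[ord],
                    frac_R = unname(frac_R[ord]), frac_E = unname(frac_E[ord]),
                    score = unname(score[ord]), stringsAsFactors = FALSE)
  out[seq_len(k), , drop = FALSE]
}
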