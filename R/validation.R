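#' Score model growth predictions against observed utilization
#'
#' Compares binary growth predictions with observed substrate utilization
#' over the strains and compounds present in both matrices (ids found in only
#' one matrix are excluded from scoring and listed in the report). Observed
#' positives are the reference: TP = predicted and observed growth, FN =
#' observed but not predicted, etc. Per-strain accuracy is
#' `100 * (TP + TN) / shared compounds`; overall accuracy pools the counts
#' over all strain-compound pairs. Per-compound false-call counts surface
#' systematic model failures (compounds every strain grows on but no model
#' predicts).
#'
#' @param pred a [presence_matrix()] of model predictions.
#' @param obs a [presence_matrix()] of observed utilization.
#' @return object of class `validation_report`: list with `per_strain` (data
#'   frame strain_id, tp, tn, fp, fn, accuracy), `per_compound` (data frame
#'   compound_id, n_false_negative, n_false_positive), `overall_accuracy`,
#'   `mean_strain_accuracy`, `predicted_core`, `observed_core`, `n_strains`,
#'   `n_compounds`, and `excluded` (ids dropped from either matrix).
#' @export
validate_predictions <- function(pred, obs) {
  pred <- as_presence(pred, "pred")
  obs <- as_presence(obs, "obs")
  strains <- intersect(rownames(pred), rownames(obs))
  compounds <- intersect(colnames(pred), colnames(obs))
  if (length(strains) == 0L || length(compounds) == 0L)
    stop("prediction and observation matrices share no ",
         if (length(strains) == 0L) "strains" else "compounds")
  excluded <- list(
    strains_pred_only = setdiff(rownames(pred), strains),
    strains_obs_only = setdiff(rownames(obs), strains),
    compounds_pred_only = setdiff(colnames(pred), compounds),
    compounds_obs_only = setdiff(colnames(obs), compounds))
  if (any(lengths(excluded) > 0))
    message("excluded from scoring: ",
            sum(lengths(excluded[1:2])), " unshared strain(s), ",
            sum(lengths(excluded[3:4])), " unshared compound(s)")
  p <- pred[strains, compounds, drop = FALSE]
  o <- obs[strains, compounds, drop = FALSE]
  tp <- rowSums(p == 1L & o == 1L)
  tn <- rowSums(p == 0L & o == 0L)
  fp <- rowSums(p == 1L & o == 0L)
  fn <- rowSums(p == 0L & o == 1L)
  shared <- length(compounds)
  per_strain <- data.frame(strain_id = strains,
                           tp = as.integer(tp), tn = as.integer(tn),
                           fp = as.integer(fp), fn = as.integer(fn),
                           accuracy = 100 * (tp + tn) / shared,
                           stringsAsFactors = FALSE, row.names = NULL)
  per_compound <- data.frame(
    compound_id = compounds,
    n_false_negative = as.integer(colSums(p == 0L & o == 1L)),
    n_false_positive = as.integer(colSums(p == 1L & o == 0L)),
    stringsAsFactors = FALSE)
  structure(list(
    per_strain = per_strain,
    per_compound = per_compound,
    overall_accuracy = 100 * sum(tp + tn) / (shared * length(strains)),
    mean_strain_accuracy = mean(per_strain$accuracy),
    predicted_core = core_compound_sets(p),
    observed_core = core_compound_sets(o),
    n_strains = length(strains), n_compounds = shared,
    excluded = excluded), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d strains x %d shared compounds\n",
              x$n_strains, x$n_compounds))
  cat(sprintf("overall accuracy %d%% (per-strain %d%%-%d%%, mean %d%%)\n",
              round(x$overall_accuracy),
              round(min(x$per_strain$accuracy)),
              round(max(x$per_strain$accuracy)),
              round(x$mean_strain_accuracy)))
  cat(sprintf("core compounds: %d predicted vs %d observed\n",
              length(x$predicted_core), length(x$observed_core)))
  invisible(x)
}

#' Compounds positive in every strain
#'
#' Column-wise AND across strains: the "core" substrate set a matrix implies
#' (predicted core for a prediction matrix, observed core for assay data).
#'
#' @param matrix a [presence_matrix()] or binary matrix.
#' @return character vector of feature ids positive in every strain.
#' @export
core_compound_sets <- function(matrix) {
  m <- as_presence(matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("matrix must be non-empty")
  colnames(m)[colSums(m) == nrow(m)]
}

#' Compartment bookkeeping of model reaction content
#'
#' Applies the same occupancy partition used for gene clusters to a
#' strains-by-reactions matrix and collapses it into the categories usually
#' reported for model comparisons: reactions common to all models (core),
#' shared between some strains of both compartments, or found only in one
#' compartment's models. `differential` is the non-core total.
#'
#' @param reactions a [presence_matrix()] (strains x model reactions).
#' @param labels a [compartment_labels()].
#' @return list with `core`, `shared`, `rhizosphere_only`, `endosphere_only`,
#'   `differential`, `total` and the underlying `venn` (`pangenome_venn`).
#' @export
reaction_venn <- function(reactions, labels) {
  venn <- partition_compartments(reactions, labels)
  cc <- venn$counts
  core <- cc["all", "all"]
  r_only <- cc["all", "none"] + cc["some", "none"]
  e_only <- cc["none", "all"] + cc["none", "some"]
  shared <- cc["all", "some"] + cc["some", "all"] + cc["some", "some"]
  list(core = core, shared = shared,
       rhizosphere_only = r_only, endosphere_only = e_only,
       differential = venn$total - core, total = venn$total,
       venn = venn)
}
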