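#' Pipeline run configuration
#'
#' @param groups,labels,alignment,traits,utilization,classes,predictions,reactions
#'   input file paths (any may be `NULL`; stages whose inputs are missing are
#'   skipped, but `labels` is required whenever any matrix stage runs).
#' @param out_dir output directory for report tables.
#' @param pathway_alpha significance level for trait/pathway enrichment
#'   (default 0.05).
#' @param group_alpha significance level for compound-class bias calls
#'   (default 0.01).
#' @param n_perm label permutations for the permutation p-values; 0 restricts
#'   reports to asymptotic p-values.
#' @param seed integer seed controlling every random draw of the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       groups = NULL, labels = NULL, alignment = NULL,
                       traits = NULL, utilization = NULL, classes = NULL,
                       predictions = NULL, reactions = NULL,
                       pathway_alpha = 0.05, group_alpha = 0.01,
                       n_perm = 1000, seed = 1L) {
  for (a in list(pathway_alpha, group_alpha))
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
      stop("alpha levels must lie strictly between 0 and 1")
  if (!is.numeric(n_perm) || n_perm < 0) stop("n_perm must be >= 0")
  if (length(seed) != 1L || is.na(suppressWarnings(as.integer(seed))))
    stop("seed must be a single integer")
  structure(list(out_dir = out_dir, groups = groups, labels = labels,
                 alignment = alignment, traits = traits,
                 utilization = utilization, classes = classes,
                 predictions = predictions, reactions = reactions,
                 pathway_alpha = pathway_alpha, group_alpha = group_alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON object may contain any [run_config()] argument; relative input
#' paths are resolved against the config file's directory.
#'
#' @param path JSON config path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("groups", "labels", "alignment", "traits", "utilization",
              "classes", "predictions", "reactions"))
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  do.call(run_config, cfg)
}

report_header <- function(config) {
  c(sprintf("rhizendo %s", as.character(utils::packageVersion("rhizendo"))),
    sprintf("seed=%d n_perm=%d pathway_alpha=%g group_alpha=%g",
            config$seed, config$n_perm, config$pathway_alpha,
            config$group_alpha))
}

# deterministic TSV writer: fixed numeric formatting, no locale dependence
write_report_tsv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  fmt <- function(v) {
    if (is.double(v)) ifelse(is.na(v), "NA", sprintf("%.6g", v))
    else ifelse(is.na(v), "NA", as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Run the full comparative analysis
#'
#' Chains every stage whose inputs are configured: core/pan occupancy Venn
#' with exclusive-pan per-genome averages, consensus similarity scoring,
#' trait enrichment, carbon-class bias and top-biased compounds, and model
#' validation (plus the reaction-content Venn). Each report is a TSV with a
#' `#` header recording the package version, seed and thresholds; two runs
#' with the same config produce byte-identical files.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return named list of stage results, invisibly; files are written to
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- report_header(config)
  labels <- if (!is.null(config$labels)) read_compartment_labels(config$labels)
  results <- list(config = config)
  need_labels <- function(stage) {
    if (is.null(labels))
      stop("stage '", stage, "' requires a compartment label table")
    labels
  }

  if (!is.null(config$groups)) {
    clusters <- read_ortholog_groups(config$groups)
    lab <- need_labels("pangenome")
    genomes <- cluster_genomes(clusters)
    unlabeled <- setdiff(genomes, names(lab))
    if (length(unlabeled))
      stop("genome(s) in groups file missing from labels: ",
           paste(unlabeled, collapse = ", "))
    presence <- presence_from_clusters(clusters, genomes)
    venn <- partition_compartments(presence, lab)
    df <- as.data.frame(venn)
    extra <- data.frame(
      occupancy_R = c("exclusive_pan_R", "exclusive_pan_E"),
      occupancy_E = c("per_genome_avg", "per_genome_avg"),
      count = c(accessory_average(venn_cell(venn, "some", "none"), venn$n_R),
                accessory_average(venn_cell(venn, "none", "some"), venn$n_E)))
    write_report_tsv(rbind(df, extra),
                     file.path(config$out_dir, "pangenome_venn.tsv"), header)
    results$pangenome <- venn
  }

  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    sim <- consensus_similarity(aln)
    write_report_tsv(sim, file.path(config$out_dir, "consensus_similarity.tsv"),
                     header)
    results$consensus <- sim
  }

  if (!is.null(config$traits)) {
    traits <- read_presence_matrix(config$traits, kind = "trait")
    lab <- need_labels("enrichment")
    enr <- enrich_traits(traits, lab, alpha = config$pathway_alpha,
                         n_perm = config$n_perm, seed = config$seed)
    write_report_tsv(enr, file.path(config$out_dir, "trait_enrichment.tsv"),
                     header)
    results$enrichment <- enr
  }

  if (!is.null(config$utilization)) {
    util <- read_presence_matrix(config$utilization, kind = "utilization")
    lab <- need_labels("carbon")
    counts <- strain_substrate_counts(util, lab)
    write_report_tsv(counts, file.path(config$out_dir, "substrate_counts.tsv"),
                     header)
    part_rows <- do.call(rbind, lapply(
      c("rhizosphere", "endosphere"), function(comp) {
        gp <- group_partition(util, names(lab)[unclass(lab) == comp])
        data.frame(compartment = comp, n_all = gp$n_all, n_none = gp$n_none,
                   n_differential = gp$n_differential)
      }))
    write_report_tsv(part_rows,
                     file.path(config$out_dir, "group_partitions.tsv"), header)
    results$substrate_counts <- counts
    results$group_partitions <- part_rows
    if (!is.null(config$classes)) {
      classes <- read_compound_classes(config$classes)
      bias <- classify_group_bias(util, lab, classes,
                                  alpha = config$group_alpha,
                                  n_perm = config$n_perm,
                                  seed = config$seed + 1000L)
      write_report_tsv(bias,
                       file.path(config$out_dir, "carbon_group_bias.tsv"),
                       header)
      results$group_bias <- bias
    }
    for (dirn in c("rhizosphere", "endosphere")) {
      top <- top_biased_compounds(util, lab, k = min(5L, ncol(util)),
                                  direction = dirn)
      write_report_tsv(top, file.path(config$out_dir,
                                      paste0("top_", dirn, "_compounds.tsv")),
                       header)
    }
  }

  if (!is.null(config$predictions)) {
    if (is.null(config$utilization))
      stop("model validation requires an observed utilization matrix")
    pred <- read_presence_matrix(config$predictions, kind = "prediction")
    obs <- read_presence_matrix(config$utilization, kind = "utilization")
    report <- suppressMessages(validate_predictions(pred, obs))
    write_report_tsv(report$per_strain,
                     file.path(config$out_dir, "model_validation.tsv"), header)
    summary <- list(
      overall_accuracy = round(report$overall_accuracy),
      mean_strain_accuracy = round(report$mean_strain_accuracy),
      n_strains = report$n_strains, n_compounds = report$n_compounds,
      n_predicted_core = length(report$predicted_core),
      n_observed_core = length(report$observed_core),
      seed = config$seed)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$validation <- report
  }

  if (!is.null(config$reactions)) {
    rx <- read_presence_matrix(config$reactions, kind = "reaction")
    lab <- need_labels("reaction_venn")
    rv <- reaction_venn(rx, lab)
    df <- data.frame(category = c("core", "shared", "rhizosphere_only",
                                  "endosphere_only", "differential", "total"),
                     count = c(rv$core, rv$shared, rv$rhizosphere_only,
                               rv$endosphere_only, rv$differential, rv$total))
    write_report_tsv(df, file.path(config$out_dir, "reaction_venn.tsv"),
                     header)
    results$reaction_venn <- rv
  }

  invisible(results)
}
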