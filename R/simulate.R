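# Seeded generators emulating the statistical structure of a two-compartment
# isolate collection: a shared core plus compartment-biased accessory gene
# families, class-structured carbon-utilization matrices with planted
# compartment effects, noisy model predictions, and marker-gene alignments
# mutated from a known consensus. Every generator is a pure function of
# (parameters, seed).

#' Default study-shaped simulation profile
#'
#' Loads the profile shipped with the package: 4 rhizosphere + 15 endosphere
#' strains, planted core/pan occupancy counts and model-reaction categories at
#' the scale of a real isolate-collection study, 190 carbon compounds in 9
#' classes with compartment-specific utilization fractions, a panel of binary
#' traits with per-compartment prevalences, a 1500-site marker gene with
#' per-site substitution rate 0.006 and a 0.24 prediction error rate.
#'
#' @return nested list of generator parameters.
#' @export
study_profile <- function() {
  jsonlite::read_json(system.file("extdata", "study_profile.json",
                                  package = "rhizendo"),
                      simplifyVector = TRUE)
}

#' Simulation ground truth
#'
#' Bundles generator parameters plus a master seed. Defaults come from
#' [study_profile()]; any field can be overridden.
#'
#' @param seed master integer seed; each generator draws from a sub-stream
#'   derived from it, so individual outputs are reproducible in isolation.
#' @param ... named overrides of profile fields (`n_R`, `n_E`, `venn_counts`,
#'   `reaction_counts`, `classes`, `traits`, `marker_length`, `mu`,
#'   `prediction_error_rate`, `n_compounds`).
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(seed = 1L, ...) {
  truth <- study_profile()
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(truth), "core_size",
                                    "accessory_size", "p_R", "p_E"))
  if (length(unknown))
    stop("unknown sim_truth field(s): ", paste(unknown, collapse = ", "))
  truth[names(dots)] <- dots
  truth$seed <- as.integer(seed)
  cl <- as.data.frame(truth$classes)
  if (any(cl$frac_R < 0 | cl$frac_R > 1 | cl$frac_E < 0 | cl$frac_E > 1))
    stop("class utilization fractions must lie in [0, 1]")
  if (!is.null(truth$n_compounds) && sum(cl$size) != truth$n_compounds)
    stop("class sizes sum to ", sum(cl$size), ", expected n_compounds = ",
         truth$n_compounds)
  if (truth$mu < 0 || truth$mu > 1) stop("mu must lie in [0, 1]")
  if (truth$prediction_error_rate < 0 || truth$prediction_error_rate > 1)
    stop("prediction_error_rate must lie in [0, 1]")
  structure(truth, class = "sim_truth")
}

sim_genomes <- function(truth)
  c(sprintf("R%02d", seq_len(truth$n_R)), sprintf("E%02d", seq_len(truth$n_E)))

sim_labels <- function(truth) {
  g <- sim_genomes(truth)
  compartment_labels(stats::setNames(
    c(rep("rhizosphere", truth$n_R), rep("endosphere", truth$n_E)), g))
}

# random subset of `pool`: size in [min_size, max_size]
rand_subset <- function(pool, min_size = 1L, max_size = length(pool)) {
  size <- if (min_size == max_size) min_size else
    sample(seq.int(min_size, max_size), 1L)
  sample(pool, size)
}

# occupancy spec ("all"/"some"/"none") -> genome subset of one compartment
occ_subset <- function(occ, pool) {
  n <- length(pool)
  switch(occ,
         all = pool,
         none = character(0),
         some = {
           if (n < 2L)
             stop("planted occupancy 'some' is impossible for a compartment of size 1")
           rand_subset(pool, 1L, n - 1L)
         })
}

VENN_CELL_OCC <- list(core = c("all", "all"),
                      all_R_some_E = c("all", "some"),
                      some_R_all_E = c("some", "all"),
                      some_some = c("some", "some"),
                      R_only = c("some", "none"),
                      E_only = c("none", "some"))

#' Generate an ortholog cluster set with planted compartment structure
#'
#' In `"exact"` mode (default) each occupancy-Venn cell receives exactly the
#' planted number of clusters (`truth$venn_counts`: `core`, `all_R_some_E`,
#' `some_R_all_E`, `some_some`, `R_only`, `E_only`), so
#' [partition_compartments()] recovers the counts exactly. In `"bernoulli"`
#' mode `truth$core_size` clusters are present everywhere and
#' `truth$accessory_size` clusters are present in each genome independently
#' with compartment probability `truth$p_R` / `truth$p_E` (clusters drawn
#' absent everywhere are re-drawn into a single random genome so every
#' cluster has at least one member).
#'
#' @param truth a [sim_truth()].
#' @param mode `"exact"` or `"bernoulli"`.
#' @return list with `clusters` ([cluster_set()]), `labels`
#'   ([compartment_labels()]) and `truth`.
#' @export
generate_pangenome <- function(truth, mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "sim_truth"))
  labels <- sim_labels(truth)
  r_pool <- names(labels)[unclass(labels) == "rhizosphere"]
  e_pool <- names(labels)[unclass(labels) == "endosphere"]
  membership <- with_seed(truth$seed + 101L, {
    if (mode == "exact") {
      counts <- truth$venn_counts
      unknown <- setdiff(names(counts), names(VENN_CELL_OCC))
      if (length(unknown))
        stop("unknown venn cell(s): ", paste(unknown, collapse = ", "))
      unlist(lapply(names(counts), function(cell) {
        occ <- VENN_CELL_OCC[[cell]]
        replicate(counts[[cell]],
                  c(occ_subset(occ[1], r_pool), occ_subset(occ[2], e_pool)),
                  simplify = FALSE)
      }), recursive = FALSE)
    } else {
      core_size <- truth$core_size %||% 3000L
      acc_size <- truth$accessory_size %||% 4000L
      p_R <- truth$p_R %||% 0.3
      p_E <- truth$p_E %||% 0.5
      core <- replicate(core_size, c(r_pool, e_pool), simplify = FALSE)
      acc <- replicate(acc_size, {
        pres <- c(r_pool[stats::runif(length(r_pool)) < p_R],
                  e_pool[stats::runif(length(e_pool)) < p_E])
        if (length(pres) == 0L) pres <- sample(c(r_pool, e_pool), 1L)
        pres
      }, simplify = FALSE)
      c(core, acc)
    }
  })
  ids <- sprintf("cl%05d", seq_along(membership))
  members <- lapply(seq_along(membership), function(i)
    data.frame(genome_id = membership[[i]],
               gene_id = rep(paste0("g", i), length(membership[[i]])),
               stringsAsFactors = FALSE))
  list(clusters = cluster_set(ids, members), labels = labels, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a class-structured carbon-utilization matrix
#'
#' Each cell (strain, compound) is an independent Bernoulli draw with success
#' probability equal to the planted utilization fraction of the strain's
#' compartment for the compound's class (`truth$classes`: `name`, `size`,
#' `frac_R`, `frac_E`).
#'
#' @param truth a [sim_truth()].
#' @return list with `util` ([presence_matrix()], strains x compounds),
#'   `classes` (named compound -> class vector), `labels` and `truth`.
#' @export
generate_utilization <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- sim_labels(truth)
  cl <- as.data.frame(truth$classes)
  compound_class <- rep(cl$name, cl$size)
  compounds <- paste0(compound_class, "_",
                      unlist(lapply(cl$size, seq_len), use.names = FALSE))
  p_R <- rep(cl$frac_R, cl$size)
  p_E <- rep(cl$frac_E, cl$size)
  genomes <- names(labels)
  m <- with_seed(truth$seed + 202L, {
    rows <- lapply(genomes, function(g) {
      p <- if (unclass(labels)[g] == "rhizosphere") p_R else p_E
      as.integer(stats::runif(length(p)) < p)
    })
    do.call(rbind, rows)
  })
  dimnames(m) <- list(genomes, compounds)
  list(util = presence_matrix(m, kind = "utilization"),
       classes = stats::setNames(compound_class, compounds),
       labels = labels, truth = truth)
}

#' Generate noisy model predictions from observed utilization
#'
#' Flips each observed cell independently with probability `error_rate`,
#' emulating an imperfect metabolic-model growth prediction.
#'
#' @param obs observed [presence_matrix()].
#' @param error_rate per-cell flip probability in [0, 1].
#' @param seed integer seed.
#' @return a [presence_matrix()] of kind `"prediction"`.
#' @export
generate_predictions <- function(obs, error_rate, seed = 1L) {
  obs <- as_presence(obs, "obs")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  flip <- with_seed(seed,
                    matrix(stats::runif(length(obs)) < error_rate, nrow(obs)))
  m <- ifelse(flip, 1L - unclass(obs), unclass(obs))
  dimnames(m) <- dimnames(obs)
  presence_matrix(m, kind = "prediction")
}

#' Generate a marker-gene alignment by mutating a consensus
#'
#' Produces `n` sequences; each site is substituted, independently with
#' probability `mu`, to one of the three other bases chosen uniformly.
#'
#' @param consensus generating sequence (string over A/C/G/T).
#' @param n number of sequences (>= 1).
#' @param mu per-site substitution probability in [0, 1].
#' @param seed integer seed.
#' @param ids optional sequence ids (default `seq001`, ...).
#' @return an [alignment()].
#' @export
generate_alignment <- function(consensus, n, mu, seed = 1L, ids = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  base <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (any(!base %in% c("A", "C", "G", "T")))
    stop("consensus must be a plain A/C/G/T sequence")
  L <- length(base)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_len(n))
  acgt <- c("A", "C", "G", "T")
  m <- with_seed(seed, {
    mm <- matrix(rep(base, each = n), nrow = n)
    hit <- which(matrix(stats::runif(n * L) < mu, nrow = n))
    if (length(hit)) {
      # uniform over the three non-current bases
      cur <- match(mm[hit], acgt)
      off <- sample.int(3L, length(hit), replace = TRUE)
      mm[hit] <- acgt[((cur - 1L + off) %% 4L) + 1L]
    }
    mm
  })
  alignment(ids, apply(m, 1L, paste, collapse = ""))
}

#' Random A/C/G/T sequence
#' @param length sequence length.
#' @param seed integer seed.
#' @return a single sequence string.
#' @export
random_sequence <- function(length, seed = 1L)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))

#' Generate a binary trait panel
#'
#' One Bernoulli draw per strain and trait, with per-compartment prevalences
#' from `truth$traits` (`name`, `prev_R`, `prev_E`).
#'
#' @param truth a [sim_truth()].
#' @return a [presence_matrix()] of kind `"trait"` (strains x traits).
#' @export
generate_traits <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- sim_labels(truth)
  tr <- as.data.frame(truth$traits)
  if (any(tr$prev_R < 0 | tr$prev_R > 1 | tr$prev_E < 0 | tr$prev_E > 1))
    stop("trait prevalences must lie in [0, 1]")
  genomes <- names(labels)
  m <- with_seed(truth$seed + 303L, {
    rows <- lapply(genomes, function(g) {
      p <- if (unclass(labels)[g] == "rhizosphere") tr$prev_R else tr$prev_E
      as.integer(stats::runif(length(p)) < p)
    })
    do.call(rbind, rows)
  })
  dimnames(m) <- list(genomes, tr$name)
  presence_matrix(m, kind = "trait")
}

#' Generate a model-reaction matrix with planted category counts
#'
#' Plants exactly `truth$reaction_counts` reactions per category: `core`
#' (present in every model), `shared` (present in at least one model of each
#' compartment, absent from at least one model overall), `R_only` / `E_only`
#' (present only in models of one compartment), so that [reaction_venn()]
#' recovers the categories exactly.
#'
#' @param truth a [sim_truth()].
#' @return list with `reactions` ([presence_matrix()]), `labels` and `truth`.
#' @export
generate_reactions <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- sim_labels(truth)
  r_pool <- names(labels)[unclass(labels) == "rhizosphere"]
  e_pool <- names(labels)[unclass(labels) == "endosphere"]
  counts <- truth$reaction_counts
  membership <- with_seed(truth$seed + 404L, c(
    replicate(counts$core, c(r_pool, e_pool), simplify = FALSE),
    replicate(counts$shared, {
      repeat {
        sr <- rand_subset(r_pool); se <- rand_subset(e_pool)
        if (length(sr) < length(r_pool) || length(se) < length(e_pool))
          break
      }
      c(sr, se)
    }, simplify = FALSE),
    replicate(counts$R_only, rand_subset(r_pool), simplify = FALSE),
    replicate(counts$E_only, rand_subset(e_pool), simplify = FALSE)))
  genomes <- names(labels)
  m <- matrix(0L, length(genomes), length(membership),
              dimnames = list(genomes,
                              sprintf("rxn%04d", seq_along(membership))))
  for (j in seq_along(membership)) m[membership[[j]], j] <- 1L
  list(reactions = presence_matrix(m, kind = "reaction"),
       labels = labels, truth = truth)
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes — ortholog groups file,
#' compartment labels, marker alignment, trait table, utilization matrix with
#' class map, model predictions and reaction matrix — and writes them, plus
#' the generating truth as JSON, into a directory.
#'
#' @param truth a [sim_truth()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
generate_bundle <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pg <- generate_pangenome(truth)
  ut <- generate_utilization(truth)
  pred <- generate_predictions(ut$util, truth$prediction_error_rate,
                               seed = truth$seed + 505L)
  rx <- generate_reactions(truth)
  traits <- generate_traits(truth)
  cons <- random_sequence(truth$marker_length, seed = truth$seed + 606L)
  aln <- generate_alignment(cons, n = truth$n_R + truth$n_E, mu = truth$mu,
                            seed = truth$seed + 707L,
                            ids = names(pg$labels))
  paths <- list(
    groups = file.path(dir, "ortholog_groups.txt"),
    labels = file.path(dir, "compartment_labels.tsv"),
    alignment = file.path(dir, "marker_alignment.fasta"),
    traits = file.path(dir, "traits.tsv"),
    utilization = file.path(dir, "utilization.tsv"),
    classes = file.path(dir, "compound_classes.tsv"),
    predictions = file.path(dir, "predictions.tsv"),
    reactions = file.path(dir, "reactions.tsv"),
    truth = file.path(dir, "truth.json"))
  # a written bundle must be loadable for any seed: the loader rejects
  # features absent from every strain, so (as in a real assay export, which
  # only lists observed features) unobserved columns are not written
  drop_unobserved <- function(m) m[, colSums(m) > 0L, drop = FALSE]
  write_ortholog_groups(pg$clusters, paths$groups)
  write_compartment_labels(pg$labels, paths$labels)
  write_alignment(aln, paths$alignment)
  write_presence_matrix(drop_unobserved(traits), paths$traits)
  util_kept <- drop_unobserved(ut$util)
  write_presence_matrix(util_kept, paths$utilization)
  kept_classes <- ut$classes[colnames(util_kept)]
  writeLines(c("compound_id\tclass",
               paste(names(kept_classes), unname(kept_classes), sep = "\t")),
             paths$classes)
  write_presence_matrix(drop_unobserved(pred), paths$predictions)
  write_presence_matrix(rx$reactions, paths$reactions)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
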