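#' Presence/absence matrix from ortholog clusters
#'
#' A genome is scored present (1) in a cluster if it contributes at least one
#' gene; paralogs collapse to a single 1. Genomes in `genomes` that never
#' occur in the clusters get all-zero rows, while a cluster that names a
#' genome outside `genomes` is an error (silently dropping members would
#' undercount the pan-genome).
#'
#' @param clusters a [cluster_set()].
#' @param genomes ordered character vector of genome ids (matrix row order).
#' @return a [presence_matrix()] (genomes x clusters).
#' @export
presence_from_clusters <- function(clusters, genomes) {
  stopifnot(inherits(clusters, "cluster_set"))
  genomes <- as.character(genomes)
  if (length(genomes) == 0L) stop("genome list must be non-empty")
  if (anyDuplicated(genomes))
    stop("duplicate genome id(s) in genome list")
  seen <- cluster_genomes(clusters)
  unknown <- setdiff(seen, genomes)
  if (length(unknown))
    stop("cluster member genome(s) not in the genome list: ",
         paste(unknown, collapse = ", "))
  m <- matrix(0L, nrow = length(genomes), ncol = length(clusters$cluster_ids),
              dimnames = list(genomes, clusters$cluster_ids))
  for (j in seq_along(clusters$members))
    m[unique(clusters$members[[j]]$genome_id), j] <- 1L
  presence_matrix(m, kind = "presence")
}

OCCUPANCY <- c("all", "some", "none")

# occupancy of one compartment group for every feature column:
# "all" = present in every member, "none" = absent from every member,
# "some" = otherwise. For a group of size 1 only "all"/"none" can occur.
occupancy_vector <- function(presence, group_strains) {
  sub <- presence[group_strains, , drop = FALSE]
  s <- colSums(sub)
  ifelse(s == nrow(sub), "all", ifelse(s == 0L, "none", "some"))
}

#' Compartment-labelled core/pan occupancy Venn
#'
#' Classifies every feature (ortholog cluster, model reaction, ...) by its
#' occupancy in each compartment group — `all` (present in every member),
#' `some`, or `none` — giving a 3x3 occupancy table. The `(all, all)` cell is
#' the core; `(some, none)` / `(none, some)` are the compartment-exclusive pan
#' genes. `(none, none)` is structurally impossible because features absent
#' from every strain are rejected at load.
#'
#' @param presence a [presence_matrix()] whose rows are all labelled strains.
#' @param labels a [compartment_labels()] covering every strain; both
#'   compartments must be non-empty.
#' @return object of class `pangenome_venn`: list with `counts` (3x3 integer
#'   matrix, rows = rhizosphere occupancy, cols = endosphere occupancy),
#'   `n_R`, `n_E`, `total`, and `assignment` (per-feature cell labels).
#' @export
partition_compartments <- function(presence, labels) {
  presence <- as_presence(presence, "presence")
  lab <- check_labels(labels, rownames(presence))
  r_strains <- rownames(presence)[lab == "rhizosphere"]
  e_strains <- rownames(presence)[lab == "endosphere"]
  occ_r <- occupancy_vector(presence, r_strains)
  occ_e <- occupancy_vector(presence, e_strains)
  if (any(occ_r == "none" & occ_e == "none"))
    stop("feature(s) absent from every labelled strain: ",
         paste(colnames(presence)[occ_r == "none" & occ_e == "none"],
               collapse = ", "))
  counts <- table(factor(occ_r, OCCUPANCY), factor(occ_e, OCCUPANCY))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(occupancy_R = OCCUPANCY,
                                   occupancy_E = OCCUPANCY))
  structure(list(counts = counts,
                 n_R = length(r_strains), n_E = length(e_strains),
                 total = ncol(presence),
                 assignment = stats::setNames(paste(occ_r, occ_e, sep = "/"),
                                              colnames(presence))),
            class = "pangenome_venn")
}

#' @export
print.pangenome_venn <- function(x, ...) {
  cat(sprintf("pangenome_venn: %d features over %d rhizosphere + %d endosphere strains\n",
              x$total, x$n_R, x$n_E))
  print(x$counts)
  cat(sprintf("core (all/all): %d; exclusive pan: rhizosphere %d, endosphere %d\n",
              venn_cell(x, "all", "all"),
              venn_cell(x, "some", "none"), venn_cell(x, "none", "some")))
  invisible(x)
}

#' Extract one occupancy cell count
#' @param venn a `pangenome_venn`.
#' @param occ_R,occ_E occupancy of the rhizosphere / endosphere group
#'   (`"all"`, `"some"` or `"none"`).
#' @return integer count.
#' @export
venn_cell <- function(venn, occ_R, occ_E) {
  stopifnot(inherits(venn, "pangenome_venn"))
  venn$counts[match.arg(occ_R, OCCUPANCY), match.arg(occ_E, OCCUPANCY)]
}

#' Venn table as a data frame
#' @param x a `pangenome_venn`.
#' @param ... unused.
#' @return data frame with columns occupancy_R, occupancy_E, count (the eight
#'   admissible cells; the structural-zero none/none cell is dropped).
#' @export
as.data.frame.pangenome_venn <- function(x, ...) {
  df <- expand.grid(occupancy_R = OCCUPANCY, occupancy_E = OCCUPANCY,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- mapply(function(r, e) x$counts[r, e],
                     df$occupancy_R, df$occupancy_E)
  df[!(df$occupancy_R == "none" & df$occupancy_E == "none"), , drop = FALSE]
}

#' Average exclusive (accessory) genes per genome
#'
#' The compartment-exclusive pan count divided by the number of genomes in
#' that compartment, rounded to the nearest integer with halves away from
#' zero (3212/15 = 214.13 -> 214; 268/4 = 67).
#'
#' @param exclusive_count non-negative integer count of exclusive clusters.
#' @param group_size number of genomes in the compartment (>= 1).
#' @return integer genes-per-genome average.
#' @export
accessory_average <- function(exclusive_count, group_size) {
  if (length(exclusive_count) != 1L || is.na(exclusive_count) ||
      exclusive_count < 0)
    stop("exclusive_count must be a single non-negative number")
  if (length(group_size) != 1L || is.na(group_size) || group_size < 1)
    stop("group_size must be a single integer >= 1")
  x <- exclusive_count / group_size
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Summarize a per-genome statistics table
#'
#' Computes the headline collection-level numbers from a table of per-genome
#' assembly statistics: mean gene count (nearest integer), genome-size range
#' endpoints (1 decimal, Mb) and the minimum marker-gene similarity.
#'
#' @param stats_df data frame with numeric columns `genome_size_mb`, `genes`
#'   and `similarity` (percent).
#' @return list with `n`, `mean_genes`, `size_range` (length-2 numeric) and
#'   `min_similarity`.
#' @export
summarize_genome_stats <- function(stats_df) {
  stats_df <- as.data.frame(stats_df)
  if (nrow(stats_df) == 0L) stop("genome statistics table is empty")
  need <- c("genome_size_mb", "genes", "similarity")
  miss <- setdiff(need, names(stats_df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  list(n = nrow(stats_df),
       mean_genes = as.integer(floor(mean(stats_df$genes) + 0.5)),
       size_range = round(range(stats_df$genome_size_mb), 1),
       min_similarity = min(stats_df$similarity))
}
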