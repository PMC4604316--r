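#' Binary strains-by-features presence/absence matrix
#'
#' Canonical container for all binary tables handled by the package: ortholog
#' cluster presence, phenotype/pathway traits, carbon-source utilization calls,
#' metabolic-model growth predictions and model reaction content. Rows are
#' strains, columns are features; cells are 0/1 integers.
#'
#' @param values matrix coercible to integer with strain row names and feature
#'   column names; every cell must be 0 or 1.
#' @param kind character scalar recording what the features are; one of
#'   `"presence"`, `"trait"`, `"utilization"`, `"prediction"`, `"reaction"`.
#' @return an integer matrix of class `presence_matrix` with a `kind`
#'   attribute.
#' @export
presence_matrix <- function(values,
                            kind = c("presence", "trait", "utilization",
                                     "prediction", "reaction")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("presence_matrix requires strain row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate strain ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("presence_matrix cells must all be 0 or 1")
  structure(values, kind = kind, class = c("presence_matrix", "matrix", "array"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix [%s]: %d strains x %d features (%d positive cells)\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# Validate/coerce an argument that should behave like a presence matrix.
# Plain binary matrices with dimnames are accepted everywhere.
as_presence <- function(x, arg = "matrix") {
  if (inherits(x, "presence_matrix")) return(x)
  if (!is.matrix(x))
    stop(arg, " must be a presence_matrix or a binary matrix with dimnames")
  presence_matrix(x, kind = "presence")
}

#' Strain-to-compartment label map
#'
#' @param x named character vector mapping genome/strain ids to
#'   `"rhizosphere"` or `"endosphere"`.
#' @return named character vector of class `compartment_labels`.
#' @export
compartment_labels <- function(x) {
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("compartment labels must be a named vector (names are genome ids)")
  if (anyDuplicated(nm))
    stop("duplicate genome ids in labels: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  vals <- as.character(unname(x))
  bad <- setdiff(unique(vals), c("rhizosphere", "endosphere"))
  if (length(bad))
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         " (expected 'rhizosphere' or 'endosphere')")
  structure(stats::setNames(vals, nm), class = "compartment_labels")
}

#' @export
print.compartment_labels <- function(x, ...) {
  cat(sprintf("compartment_labels: %d strains (%d rhizosphere, %d endosphere)\n",
              length(x), sum(unclass(x) == "rhizosphere"),
              sum(unclass(x) == "endosphere")))
  invisible(x)
}

# Check that labels cover `strains`, error listing offenders, and that both
# compartments are non-empty among those strains. Returns the label subset in
# strain order.
check_labels <- function(labels, strains, require_both = TRUE) {
  if (!inherits(labels, "compartment_labels")) labels <- compartment_labels(labels)
  missing <- setdiff(strains, names(labels))
  if (length(missing))
    stop("strain id(s) missing from compartment labels: ",
         paste(missing, collapse = ", "))
  lab <- unclass(labels)[strains]
  if (require_both) {
    for (comp in c("rhizosphere", "endosphere"))
      if (!any(lab == comp))
        stop("compartment '", comp, "' has zero strains")
  }
  lab
}

#' Ortholog cluster set
#'
#' Holds the output of an ortholog clustering run in the common groups-file
#' shape: an ordered list of clusters, each a set of (genome, gene) members.
#'
#' @param cluster_ids character vector of unique cluster ids, in file order.
#' @param members list (same length) of data frames with columns `genome_id`
#'   and `gene_id`; each cluster must have at least one member.
#' @return object of class `cluster_set`.
#' @export
cluster_set <- function(cluster_ids, members) {
  cluster_ids <- as.character(cluster_ids)
  if (length(cluster_ids) != length(members))
    stop("cluster_ids and members must have equal length")
  if (anyDuplicated(cluster_ids))
    stop("duplicate cluster id(s): ",
         paste(unique(cluster_ids[duplicated(cluster_ids)]), collapse = ", "))
  members <- lapply(members, function(m) {
    m <- as.data.frame(m)
    if (!all(c("genome_id", "gene_id") %in% names(m)))
      stop("each member table needs genome_id and gene_id columns")
    m <- unique(m[c("genome_id", "gene_id")])
    if (nrow(m) == 0L) stop("every cluster must have at least one member")
    m
  })
  if (length(members)) {
    key <- unlist(lapply(members, function(m)
      paste(m$genome_id, m$gene_id, sep = "\r")), use.names = FALSE)
    if (anyDuplicated(key))
      stop("gene(s) assigned to more than one cluster: ",
           paste(unique(sub("\r", "|", key[duplicated(key)])), collapse = ", "))
  }
  structure(list(cluster_ids = cluster_ids, members = members),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  n_mem <- sum(vapply(x$members, nrow, integer(1)))
  cat(sprintf("cluster_set: %d clusters, %d gene members, %d genomes\n",
              length(x$cluster_ids), n_mem,
              length(unique(unlist(lapply(x$members, `[[`, "genome_id"))))))
  invisible(x)
}

#' @export
length.cluster_set <- function(x) length(x$cluster_ids)

#' Genomes named in a cluster set
#' @param clusters a [cluster_set()].
#' @return sorted character vector of genome ids occurring in any cluster.
#' @export
cluster_genomes <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  sort(unique(unlist(lapply(clusters$members, `[[`, "genome_id"))))
}

#' Aligned marker-gene sequences
#'
#' A light container for a pre-aligned nucleotide alignment over the alphabet
#' `A C G T N -`. The package does not compute alignments.
#'
#' @param ids unique sequence ids.
#' @param sequences character vector of aligned sequences, all the same length.
#' @return object of class `alignment` (named character vector).
#' @export
alignment <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences) || length(ids) < 1L)
    stop("need at least one sequence, with one id per sequence")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- nchar(sequences)
  if (length(unique(w)) != 1L)
    stop("all sequences must have equal aligned length (got ",
         paste(sort(unique(w)), collapse = ", "), ")")
  if (w[1] < 1L) stop("alignment length must be >= 1")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequence(s) with symbols outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "))
  structure(stats::setNames(sequences, ids), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns\n",
              length(x), nchar(unclass(x)[1])))
  invisible(x)
}

# character matrix (sequences x columns) view of an alignment
aln_matrix <- function(aln) {
  s <- unclass(aln)
  matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
         nrow = length(s), byrow = TRUE,
         dimnames = list(names(s), NULL))
}
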