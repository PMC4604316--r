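#' Read an ortholog groups file
#'
#' Parses the common groups-file dialect produced by ortholog clustering
#' tools: one cluster per line, `cluster_id: genomeA|gene1 genomeB|gene2 ...`.
#' The genome id is the token before the first `|`; any further `|` characters
#' belong to the gene id.
#'
#' @param path path to a groups text file.
#' @return a [cluster_set()] preserving file order. An empty file yields an
#'   empty cluster set.
#' @export
read_ortholog_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  ids <- character(0)
  members <- list()
  for (i in keep) {
    line <- lines[i]
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L)
      stop("parse error at line ", i, ": no ':' separating cluster id (", path, ")")
    id <- trimws(substr(line, 1L, colon - 1L))
    if (!nzchar(id))
      stop("parse error at line ", i, ": empty cluster id (", path, ")")
    rest <- trimws(substring(line, colon + 1L))
    toks <- strsplit(rest, "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
      stop("parse error at line ", i, ": cluster '", id, "' has no members")
    bar <- regexpr("|", toks, fixed = TRUE)
    if (any(bar < 1L))
      stop("parse error at line ", i, ": member(s) without 'genome|gene' form: ",
           paste(toks[bar < 1L], collapse = ", "))
    ids <- c(ids, id)
    members[[length(members) + 1L]] <- data.frame(
      genome_id = substr(toks, 1L, bar - 1L),
      gene_id = substring(toks, bar + 1L),
      stringsAsFactors = FALSE)
  }
  cluster_set(ids, members)
}

#' Write an ortholog groups file
#' @param clusters a [cluster_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_groups <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  lines <- vapply(seq_along(clusters$cluster_ids), function(i) {
    m <- clusters$members[[i]]
    paste0(clusters$cluster_ids[i], ": ",
           paste(m$genome_id, m$gene_id, sep = "|", collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary strains-by-features TSV matrix
#'
#' First row holds feature ids, first column strain ids. Cells must be 0/1
#' unless `tokens` declares alternative truthy/falsy symbols (e.g. `"+"`/`"-"`
#' as exported by some phenotype-microarray software). Features absent from
#' every strain are rejected: they carry no information and break the
#' occupancy partition's assumption that every feature exists somewhere.
#'
#' @param path TSV path. Lines starting with `#` are ignored.
#' @param kind matrix kind, as in [presence_matrix()].
#' @param tokens optional `c(positive = "+", negative = "-")` token map; when
#'   `NULL` (default) cells must be literal 0/1.
#' @return a [presence_matrix()].
#' @export
read_presence_matrix <- function(path,
                                 kind = c("presence", "trait", "utilization",
                                          "prediction", "reaction"),
                                 tokens = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#", fill = FALSE,
                          blank.lines.skip = TRUE)
  if (ncol(df) < 2L) stop("matrix file needs a strain id column plus >=1 feature: ", path)
  strains <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- strains
  if (!is.null(tokens)) {
    if (!all(c("positive", "negative") %in% names(tokens)))
      stop("tokens must be a named vector with 'positive' and 'negative'")
    m[m == tokens[["positive"]]] <- "1"
    m[m == tokens[["negative"]]] <- "0"
  }
  bad <- which(!(m %in% c("0", "1")))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop("non-binary cell '", m[bad[1]], "' at strain '", rownames(m)[i],
         "', feature '", colnames(m)[j], "' in ", path)
  }
  storage.mode(m) <- "integer"
  empty <- colnames(m)[colSums(m) == 0L]
  if (length(empty))
    stop("feature(s) absent from every strain: ",
         paste(empty, collapse = ", "), " in ", path)
  presence_matrix(m, kind = kind)
}

#' Write a presence matrix as TSV
#'
#' @param x a [presence_matrix()] or binary matrix.
#' @param path output path.
#' @param comment optional character vector written as leading `# ` lines
#'   (used by the pipeline to record version, seed and thresholds).
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(x, path, comment = NULL) {
  x <- as_presence(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("strain_id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[i], x[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a strain-to-compartment label table
#'
#' @param path two-column TSV (`genome_id`, `compartment`), with or without a
#'   header line. Compartment values are matched case-insensitively against
#'   `rhizosphere` / `endosphere`.
#' @return a [compartment_labels()] vector.
#' @export
read_compartment_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 2L) stop("label file needs two tab-separated columns: ", path)
  if (tolower(df[1, 2]) %in% c("compartment", "isolation_compartment"))
    df <- df[-1, , drop = FALSE]
  compartment_labels(stats::setNames(tolower(df[[2]]), df[[1]]))
}

#' Write a strain-to-compartment label table
#' @param labels a [compartment_labels()] vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compartment_labels <- function(labels, path) {
  writeLines(c("genome_id\tcompartment",
               paste(names(labels), unclass(labels), sep = "\t")), path)
  invisible(path)
}

#' Read an aligned FASTA file
#' @param path FASTA path; records must all have the same aligned length.
#' @return an [alignment()].
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  alignment(names(x), as.character(x))
}

#' Write an alignment as FASTA
#' @param aln an [alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  x <- Biostrings::DNAStringSet(unclass(aln))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a compound-to-class map
#' @param path two-column TSV (`compound_id`, `class`), optional header.
#' @return named character vector compound -> class.
#' @export
read_compound_classes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 2L) stop("class map needs two tab-separated columns: ", path)
  if (tolower(df[1, 2]) %in% c("class", "class_name", "group"))
    df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    stop("compound(s) classified more than once: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}
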