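#' Read a disease-microbe association edge list
#'
#' Tab-separated file with two columns `disease_id<TAB>microbe_id`; a
#' header line is auto-detected ("disease"/"microbe" in the first row),
#' `#` comment lines are skipped, duplicate pairs are collapsed with a
#' warning.  Labels are ordered by first appearance.
#'
#' @param path file path.
#' @return an [association_matrix()].
#' @export
read_association_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # optional label-inventory comments (written by write_association_table)
  # preserve entities with no associations across a round trip
  inv <- function(tag) {
    hit <- grep(paste0("^#\\s*", tag, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    strsplit(sub(paste0("^#\\s*", tag, ":\\s*"), "", hit[1]), ",", fixed = TRUE)[[1]]
  }
  dis_inv <- inv("diseases")
  mic_inv <- inv("microbes")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty association file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated columns",
                 bad[1], path))
  d <- vapply(fields, `[[`, "", 1L)
  m <- vapply(fields, `[[`, "", 2L)
  if (grepl("disease", d[1], ignore.case = TRUE) &&
      grepl("microbe", m[1], ignore.case = TRUE)) {
    d <- d[-1]; m <- m[-1]
  }
  if (length(d) == 0 && (is.null(dis_inv) || is.null(mic_inv)))
    stop(sprintf("no association pairs in %s", path))
  dup <- duplicated(paste(d, m, sep = "\t"))
  if (any(dup)) {
    warning(sprintf("%d duplicate pair(s) collapsed in %s", sum(dup), path))
    d <- d[!dup]; m <- m[!dup]
  }
  dis <- if (!is.null(dis_inv)) dis_inv else unique(d)
  mic <- if (!is.null(mic_inv)) mic_inv else unique(m)
  if (!all(d %in% dis) || !all(m %in% mic))
    stop(sprintf("pair label absent from the label inventory in %s", path))
  A <- matrix(0, length(dis), length(mic), dimnames = list(dis, mic))
  A[cbind(match(d, dis), match(m, mic))] <- 1
  association_matrix(A, dis, mic)
}

#' Write an association matrix as an edge list
#'
#' @param A an [association_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(A, path) {
  idx <- which(as.matrix(A) == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  # lead with a label inventory so isolated entities survive the round trip
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# diseases: ", paste(rownames(A), collapse = ",")),
               paste0("# microbes: ", paste(colnames(A), collapse = ",")),
               "disease_id\tmicrobe_id",
               paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]],
                     sep = "\t")),
             con)
  invisible(path)
}

#' Read a labelled square similarity matrix
#'
#' First row and first column carry entity ids.  Asymmetries up to 1e-8
#' are silently averaged away; larger ones are symmetrized with a warning.
#' Entries outside \[0, 1\] are clipped with a warning.
#'
#' @param path file path.
#' @param kind similarity kind recorded on the result.
#' @return a `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path, kind = "functional") {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                          comment.char = "#")
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop(sprintf("non-square matrix in %s", path))
  if (!identical(rownames(M), colnames(M)))
    stop(sprintf("row and column labels differ in %s", path))
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8) {
    warning(sprintf("asymmetry %.3g in %s; symmetrized by averaging", asym, path))
  }
  M <- (M + t(M)) / 2
  if (min(M) < 0 || max(M) > 1) {
    warning(sprintf("entries outside [0, 1] in %s clipped", path))
    M <- pmin(pmax(M, 0), 1)
  }
  similarity_matrix(M, rownames(M), kind = kind)
}

#' Write a similarity (or any labelled square) matrix as labelled TSV
#'
#' @param S matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(S, path) {
  M <- as.matrix(S)
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read an entity-to-gene annotation table
#'
#' TSV with columns `entity_id<TAB>gene_id`; `#` comments skipped, header
#' auto-detected.
#'
#' @param path file path.
#' @return named list: entity id -> character vector of gene ids.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("expected 2 columns in %s", path))
  if (grepl("entity|disease|microbe", df[1, 1], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  split(df[[2]], df[[1]])[unique(df[[1]])]
}

#' Read a gene-gene score network and normalize it
#'
#' TSV with columns `gene_id<TAB>gene_id<TAB>score` of raw (e.g.
#' log-likelihood) scores; scores are min-max normalized to \[0, 1\] via
#' [normalize_lls()].
#'
#' @param path file path.
#' @return a `gene_net`.
#' @export
read_gene_net <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = c("character", "character", "numeric"))
  if (ncol(df) < 3L) stop(sprintf("expected 3 columns in %s", path))
  normalize_lls(df)
}

#' Validate a raw configuration list
#'
#' Accepts a named list (e.g. parsed from YAML or JSON), fills defaults
#' from [mdagcan_config()], rejects unknown keys, wrong types and
#' out-of-range values.
#'
#' @param raw named list of configuration overrides.
#' @return an [mdagcan_config()].
#' @export
validate_config <- function(raw = list()) {
  if (is.null(raw)) raw <- list()
  legal <- names(formals(mdagcan_config))
  unknown <- setdiff(names(raw), legal)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (k in names(raw))
    if (!is.numeric(raw[[k]]) || length(raw[[k]]) != 1L)
      stop(sprintf("config key '%s' must be a single number", k))
  do.call(mdagcan_config, raw)
}

#' Read a YAML or JSON configuration file
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an [mdagcan_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(as.list(raw))
}
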