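#' Construct a binary disease-by-microbe association matrix
#'
#' The association matrix `A` has one row per disease and one column per
#' microbe; `A[i, j] = 1` records a known association between disease `i`
#' and microbe `j`, and 0 an unobserved pair.
#'
#' @param values numeric matrix with entries in \{0, 1\}.
#' @param disease_ids character vector of unique row labels; defaults to
#'   existing rownames or `d1, d2, ...`.
#' @param microbe_ids character vector of unique column labels; defaults to
#'   existing colnames or `m1, m2, ...`.
#' @return an object of class `association_matrix`: a labelled binary
#'   integer matrix.
#' @export
association_matrix <- function(values, disease_ids = NULL, microbe_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("association matrix needs at least one disease and one microbe")
  if (!all(values %in% c(0, 1)))
    stop("association matrix entries must be 0 or 1")
  if (is.null(disease_ids)) disease_ids <- rownames(values)
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(nrow(values)))
  if (is.null(microbe_ids)) microbe_ids <- colnames(values)
  if (is.null(microbe_ids)) microbe_ids <- paste0("m", seq_len(ncol(values)))
  disease_ids <- as.character(disease_ids)
  microbe_ids <- as.character(microbe_ids)
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids")
  if (anyDuplicated(microbe_ids)) stop("duplicate microbe ids")
  if (length(disease_ids) != nrow(values) || length(microbe_ids) != ncol(values))
    stop("label lengths do not match matrix dimensions")
  storage.mode(values) <- "double"
  dimnames(values) <- list(disease_ids, microbe_ids)
  structure(values, class = c("association_matrix", "matrix", "array"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d diseases x %d microbes, %d known associations (density %.4f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

is_association_matrix <- function(x) inherits(x, "association_matrix")

as_plain_matrix <- function(x) {
  class(x) <- c("matrix", "array")
  x
}
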