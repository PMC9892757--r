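#' Gaussian interaction profile (GIP) kernel bandwidth
#'
#' The kernel bandwidth is the original bandwidth `lambda_prime` divided by
#' the mean squared Euclidean norm of the interaction profiles, so that the
#' kernel adapts to the density of known associations.
#'
#' @param profiles matrix whose *columns* are binary interaction profiles,
#'   or a list of equal-length binary vectors.
#' @param lambda_prime original bandwidth (default 1).
#' @return positive scalar bandwidth.
#' @export
gip_bandwidth <- function(profiles, lambda_prime = 1) {
  if (is.list(profiles)) {
    lens <- lengths(profiles)
    if (length(profiles) < 1L) stop("need at least one profile")
    if (length(unique(lens)) != 1L) stop("profiles must have equal length")
    profiles <- do.call(cbind, profiles)
  }
  profiles <- as.matrix(profiles)
  mean_sq <- mean(colSums(profiles^2))
  if (mean_sq == 0)
    stop("bandwidth undefined: no known associations")
  lambda_prime / mean_sq
}

#' GIP kernel similarity from an association matrix
#'
#' Computes `exp(-lambda * ||p_i - p_j||^2)` for every pair of entities,
#' where the profiles `p` are columns of the association matrix for microbes
#' and rows for diseases, and `lambda` comes from [gip_bandwidth()].
#'
#' @param A an [association_matrix()].
#' @param axis `"microbe"` (column profiles) or `"disease"` (row profiles).
#' @param lambda_prime original bandwidth (default 1).
#' @return a `similarity_matrix` of kind `"gip"`.
#' @export
gip_similarity <- function(A, axis = c("microbe", "disease"), lambda_prime = 1) {
  axis <- match.arg(axis)
  A <- as_plain_matrix(as.matrix(A))
  profiles <- if (axis == "microbe") A else t(A)  # columns are profiles
  lambda <- gip_bandwidth(profiles, lambda_prime)
  # ||p_i - p_j||^2 = |p_i| + |p_j| - 2 p_i . p_j  for binary profiles
  nrm <- colSums(profiles^2)
  sq <- outer(nrm, nrm, "+") - 2 * crossprod(profiles)
  sq[sq < 0] <- 0  # numerical guard
  K <- exp(-lambda * sq)
  K <- (K + t(K)) / 2
  ids <- colnames(profiles)
  similarity_matrix(K, entity_ids = ids, kind = "gip")
}

#' Construct a labelled symmetric similarity matrix
#'
#' @param values square numeric matrix, symmetric within 1e-8, entries in
#'   \[0, 1\].
#' @param entity_ids ordered labels; defaults to existing dimnames.
#' @param kind one of `"gip"`, `"functional"`, `"integrated"`.
#' @return object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values,
                              entity_ids = NULL,
                              kind = c("gip", "functional", "integrated")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("similarity matrix must be symmetric")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    stop("similarity entries must lie in [0, 1]")
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  if (is.null(entity_ids)) entity_ids <- rownames(values)
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(nrow(values)))
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop("duplicate entity ids")
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(values, kind = kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d entities, mean off-diagonal %.4f\n",
              attr(x, "kind"), nrow(x),
              mean(x[row(x) != col(x)])))
  invisible(x)
}

#' Fuse GIP and functional similarity
#'
#' Entry-wise conditional fusion: where the functional similarity is zero
#' (no functional evidence) the GIP value is kept unchanged; elsewhere the
#' convex combination `mu * gip + (1 - mu) * functional` is used.
#'
#' @param gip,functional `similarity_matrix` objects over the same entities
#'   in the same order.
#' @param mu weight on the GIP similarity, in \[0, 1\].
#' @return a `similarity_matrix` of kind `"integrated"`.
#' @export
integrate_similarity <- function(gip, functional, mu) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (!identical(rownames(gip), rownames(functional)))
    stop("entity labels of the two similarity matrices do not match")
  g <- as_plain_matrix(as.matrix(gip))
  f <- as_plain_matrix(as.matrix(functional))
  out <- ifelse(f == 0, g, mu * g + (1 - mu) * f)
  similarity_matrix(out, entity_ids = rownames(gip), kind = "integrated")
}
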