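#' Build a normalized gene-gene functional network
#'
#' Raw log-likelihood-style scores on gene pairs are min-max rescaled to
#' \[0, 1\] over the observed off-diagonal scores; every gene's self-score
#' is fixed at 1 (a gene is maximally associated with itself), so the
#' best-match-average similarity of identical annotation sets is 1.  Pairs
#' absent from the network score 0 (no evidence).
#'
#' @param pairs data frame (or 3-column matrix) with columns gene a, gene b,
#'   raw score.
#' @return object of class `gene_net`.
#' @export
normalize_lls <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 3L) stop("need columns: gene_a, gene_b, score")
  ga <- as.character(pairs[[1]])
  gb <- as.character(pairs[[2]])
  s <- as.numeric(pairs[[3]])
  if (length(s) < 1L) stop("need at least one score")
  if (any(!is.finite(s))) stop("non-finite raw scores")
  off <- ga != gb
  scores <- numeric(0)
  if (any(off)) {
    so <- s[off]
    rng <- range(so)
    norm <- if (rng[1] == rng[2]) rep(1, length(so)) else (so - rng[1]) / diff(rng)
    scores <- norm
    names(scores) <- gene_pair_key(ga[off], gb[off])
    # symmetric duplicates: keep the maximum (defensive; inputs are usually unique)
    scores <- tapply(scores, names(scores), max)
    scores <- stats::setNames(as.numeric(scores), names(scores))
  }
  genes <- sort(unique(c(ga, gb)))
  structure(list(scores = scores, genes = genes), class = "gene_net")
}

gene_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up normalized scores for gene pairs
#'
#' @param net a `gene_net`.
#' @param a,b character vectors of gene ids (recycled).
#' @return numeric vector of scores; self pairs give 1, unknown pairs 0.
#' @export
gene_net_score <- function(net, a, b) {
  stopifnot(inherits(net, "gene_net"))
  a <- as.character(a); b <- as.character(b)
  out <- ifelse(a == b, 1, 0)
  idx <- which(a != b)
  if (length(idx)) {
    hit <- net$scores[gene_pair_key(a[idx], b[idx])]
    hit[is.na(hit)] <- 0
    out[idx] <- hit
  }
  unname(out)
}

#' @export
print.gene_net <- function(x, ...) {
  cat(sprintf("gene_net: %d genes, %d scored pairs\n",
              length(x$genes), length(x$scores)))
  invisible(x)
}

#' Best-match-average (BMA) functional similarity of two entities
#'
#' For annotation sets `G^a` (size m) and `G^b` (size n), each gene is
#' matched to its best-scoring partner in the opposite set and the matches
#' are averaged over both directions:
#' `(sum_x max_y s(x, y) + sum_y max_x s(x, y)) / (m + n)`.
#' An entity missing from the annotation map contributes no functional
#' evidence and the similarity is 0, which triggers the pure-GIP fallback
#' in [integrate_similarity()].
#'
#' @param map named list: entity id -> character vector of gene ids.
#' @param net a `gene_net` from [normalize_lls()].
#' @param entity_a,entity_b entity ids.
#' @return similarity in \[0, 1\].
#' @export
bma_functional_similarity <- function(map, net, entity_a, entity_b) {
  ga <- map[[entity_a]]
  gb <- map[[entity_b]]
  if (is.null(ga) || is.null(gb) || length(ga) == 0L || length(gb) == 0L)
    return(0)
  ga <- unique(as.character(ga)); gb <- unique(as.character(gb))
  S <- matrix(gene_net_score(net,
                             rep(ga, times = length(gb)),
                             rep(gb, each = length(ga))),
              nrow = length(ga))
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (length(ga) + length(gb))
}

#' Full functional similarity matrix over a set of entities
#'
#' @param map named list: entity id -> gene ids (entities without
#'   annotations may be absent).
#' @param net a `gene_net`.
#' @param entity_ids ordered entity labels defining the output rows/columns.
#' @return a `similarity_matrix` of kind `"functional"`; unannotated
#'   entities have 0 similarity to everything (diagonal included), so the
#'   fused similarity falls back to GIP there.
#' @export
functional_similarity <- function(map, net, entity_ids) {
  n <- length(entity_ids)
  out <- matrix(0, n, n, dimnames = list(entity_ids, entity_ids))
  annotated <- which(entity_ids %in% names(map))
  for (ii in seq_along(annotated)) {
    i <- annotated[ii]
    for (j in annotated[seq_len(ii)]) {
      v <- bma_functional_similarity(map, net, entity_ids[i], entity_ids[j])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  similarity_matrix(out, entity_ids = entity_ids, kind = "functional")
}
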