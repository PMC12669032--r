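# Chemical-space statistics on binary fingerprints: Tanimoto similarity,
# nearest-library coverage, threshold counts, KS coverage comparison and
# binary-profile distance matrices.

#' Tanimoto (Jaccard) similarity of two bit sets
#'
#' \code{|a intersect b| / |a union b|}; defined as 0 when both sets are
#' empty. Symmetric, bounded in [0, 1], equal to 1 iff the nonempty sets are
#' identical.
#'
#' @param a,b integer vectors of set-bit indices.
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto <- function(a, b) {
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0L) 0 else ni / nu
}

# dense 0/1 matrix from a FingerprintSet (compounds x bits)
.fpMatrix <- function(fps) {
  bits <- fpBits(fps)
  m <- matrix(0L, length(bits), fps@nbits,
              dimnames = list(names(bits), NULL))
  for (i in seq_along(bits)) m[i, bits[[i]] + 1L] <- 1L
  m
}

#' Closest-match similarity of queries against a library
#'
#' For every query fingerprint, the maximum Tanimoto similarity over the
#' library and the identity of the nearest library member (ties broken by
#' the first id in sorted order). This is the coverage statistic used to ask
#' how well a screening library spans a larger chemical space.
#'
#' @param queries a \linkS4class{FingerprintSet}.
#' @param library a nonempty \linkS4class{FingerprintSet} of the same bit
#'   length.
#' @return data.frame with \code{query_id}, \code{max_similarity},
#'   \code{nearest_id}.
#' @export
maxSimilarity <- function(queries, library) {
  .stopIfNot(length(library) >= 1L, "library must be non-empty")
  .stopIfNot(queries@nbits == library@nbits,
             "fingerprint lengths must match")
  Q <- .fpMatrix(queries)
  L <- .fpMatrix(library)
  L <- L[order(rownames(L)), , drop = FALSE]  # sorted ids for tie-breaks
  inter <- Q %*% t(L)
  uni <- outer(rowSums(Q), rowSums(L), `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  best <- apply(sim, 1L, which.max)  # first maximum = sorted-order tie-break
  data.frame(query_id = rownames(Q),
             max_similarity = sim[cbind(seq_len(nrow(sim)), best)],
             nearest_id = rownames(L)[best])
}

#' Count similarities strictly above a threshold
#'
#' @param similarities numeric vector in [0, 1].
#' @param threshold cutoff, default 0.75.
#' @return integer count of values strictly greater than the threshold.
#' @export
countAbove <- function(similarities, threshold = 0.75) {
  .stopIfNot(all(similarities >= 0 & similarities <= 1),
             "similarities must lie in [0, 1]")
  sum(similarities > threshold)
}

#' Two-sample Kolmogorov-Smirnov comparison of coverage distributions
#'
#' Compares two samples of closest-match similarities with the two-sided
#' two-sample KS test (D = supremum ECDF difference; asymptotic p, suited
#' to the hundreds-to-thousands of compounds typical here).
#'
#' @param dist_a,dist_b numeric samples.
#' @return list with \code{D} and \code{p}.
#' @export
ksCoverageTest <- function(dist_a, dist_b) {
  .stopIfNot(length(dist_a) >= 1L && length(dist_b) >= 1L,
             "both samples must be non-empty")
  kt <- suppressWarnings(ks.test(dist_a, dist_b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Jaccard distance matrix of binary profiles
#'
#' Symmetric matrix of \code{1 - tanimoto} distances between binary
#' profiles (e.g. per-strain inhibition profiles), with zero diagonal.
#'
#' @param profiles named list of integer vectors (set positions) or a
#'   \linkS4class{FingerprintSet}.
#' @return symmetric numeric distance matrix.
#' @export
binaryProfileDistances <- function(profiles) {
  if (is(profiles, "FingerprintSet")) profiles <- fpBits(profiles)
  .stopIfNot(length(profiles) >= 2L, "need >= 2 profiles")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - tanimoto(profiles[[i]], profiles[[j]])
    }
  }
  d
}
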