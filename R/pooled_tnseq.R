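# Per-gene fitness analysis of pooled barcoded transposon libraries:
# trimmed-total-read-count normalization, central-CDS site masking,
# permutation resampling, doublings correction and pathway enrichment.

#' @import SummarizedExperiment
NULL

#' InsertionExperiment: insertion site x sample read counts
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose rows are
#' transposon insertion sites (rowData: \code{position} 1-based,
#' \code{gene_id} or NA for intergenic, \code{barcode_id}) and whose columns
#' are sequenced samples (colData: \code{condition}, \code{replicate},
#' \code{doublings}). The single assay \code{"counts"} holds nonnegative
#' integer read counts.
#'
#' @aliases InsertionExperiment
#' @exportClass InsertionExperiment
setClass("InsertionExperiment", contains = "SummarizedExperiment")

setValidity("InsertionExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  rd <- rowData(object)
  if (!all(c("position", "gene_id", "barcode_id") %in% colnames(rd)))
    msg <- c(msg, "rowData needs position, gene_id, barcode_id")
  else if (any(rd$position < 1))
    msg <- c(msg, "site positions must be >= 1 (1-based)")
  cd <- colData(object)
  if (!all(c("condition", "replicate", "doublings") %in% colnames(cd)))
    msg <- c(msg, "colData needs condition, replicate, doublings")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an InsertionExperiment
#'
#' @param counts site x sample matrix of nonnegative integer read counts.
#' @param position 1-based insertion site coordinates.
#' @param gene_id gene assignment per site (NA for intergenic).
#' @param barcode_id barcode identifier per site.
#' @param condition,replicate,doublings per-sample annotations.
#' @return an \linkS4class{InsertionExperiment}.
#' @export
InsertionExperiment <- function(counts, position, gene_id, barcode_id,
                                condition, replicate, doublings) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(position = as.integer(position),
                        gene_id = as.character(gene_id),
                        barcode_id = as.character(barcode_id)),
    colData = DataFrame(condition = as.character(condition),
                        replicate = as.integer(replicate),
                        doublings = as.numeric(doublings),
                        row.names = colnames(counts)))
  new("InsertionExperiment", se)
}

#' Central-CDS site mask
#'
#' Keeps insertion sites in the central 80 percent of a coding region:
#' with fractional offset \code{f = (position - start) / (end - start + 1)},
#' sites with \code{0.1 <= f < 0.9} are retained. Sites outside the gene are
#' never retained.
#'
#' @param position site coordinate(s), 1-based.
#' @param start,end 1-based inclusive gene coordinates.
#' @return logical vector: TRUE for retained sites.
#' @examples
#' centralMask(50, 1, 100)  # TRUE
#' centralMask(5, 1, 100)   # FALSE (5' tail)
#' @export
centralMask <- function(position, start, end) {
  .stopIfNot(all(start <= end, na.rm = TRUE), "gene start must be <= end")
  f <- (position - start) / (end - start + 1)
  position >= start & position <= end & f >= 0.1 & f < 0.9
}

#' Trimmed-total-read-count (TTR) normalization
#'
#' Per sample, the mean of nonzero site counts is computed after discarding
#' the top and bottom 5 percent of nonzero values; each sample is scaled so
#' its trimmed mean equals the across-sample grand trimmed mean. Robust to
#' single jackpot sites, corrects sequencing depth.
#'
#' @param counts site x sample count matrix.
#' @param trim fraction trimmed from each tail of the nonzero counts,
#'   default 0.05.
#' @param min_nonzero minimum nonzero sites per sample, default 20.
#' @return list with \code{normalized} (matrix) and \code{factors}
#'   (per-sample scale factors).
#' @export
ttrNormalize <- function(counts, trim = 0.05, min_nonzero = 20L) {
  counts <- as.matrix(counts)
  nz <- colSums(counts > 0)
  if (any(nz == 0L)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[nz == 0L], collapse = ", "), call. = FALSE)
  }
  .stopIfNot(all(nz >= min_nonzero),
             "each sample needs >= ", min_nonzero, " nonzero sites")
  tmean <- vapply(seq_len(ncol(counts)), function(j) {
    x <- sort(counts[counts[, j] > 0, j])
    k <- floor(trim * length(x))
    if (2L * k >= length(x)) k <- 0L
    mean(x[(k + 1L):(length(x) - k)])
  }, numeric(1))
  grand <- mean(tmean)
  factors <- grand / tmean
  names(factors) <- colnames(counts)
  normalized <- sweep(counts, 2L, factors, `*`)
  list(normalized = normalized, factors = factors)
}

#' Aggregate site counts to gene level
#'
#' Sums normalized counts over each gene's retained (central-80-percent)
#' sites. Genes with zero retained sites are reported untestable; all
#' remaining sites (intergenic or masked tails) are pooled into an
#' \code{intergenic} total so that genes + intergenic conserve the site
#' total.
#'
#' @param normCounts normalized site x sample matrix.
#' @param sites data.frame with \code{position} and \code{gene_id} per site
#'   (row order matching \code{normCounts}).
#' @param geneTable data.frame with \code{gene_id}, \code{start}, \code{end}
#'   (1-based inclusive), \code{strand}.
#' @return list with \code{geneCounts} (gene x sample matrix),
#'   \code{untestable} (gene ids with no retained site), \code{intergenic}
#'   (per-sample totals of unassigned counts) and \code{retained} (logical
#'   per site).
#' @export
geneAggregate <- function(normCounts, sites, geneTable) {
  .stopIfNot(!anyDuplicated(geneTable$gene_id), "gene_ids must be unique")
  .stopIfNot(all(geneTable$start <= geneTable$end), "gene start must be <= end")
  gidx <- match(sites$gene_id, geneTable$gene_id)
  retained <- !is.na(gidx) & centralMask(sites$position,
                                         geneTable$start[gidx],
                                         geneTable$end[gidx])
  gene_f <- factor(sites$gene_id[retained], levels = geneTable$gene_id)
  gc <- rowsum(normCounts[retained, , drop = FALSE], gene_f)
  # rowsum drops absent levels; reinstate untestable genes as missing
  full <- matrix(NA_real_, nrow(geneTable), ncol(normCounts),
                 dimnames = list(geneTable$gene_id, colnames(normCounts)))
  full[rownames(gc), ] <- gc
  untestable <- geneTable$gene_id[!geneTable$gene_id %in% rownames(gc)]
  intergenic <- colSums(normCounts[!retained, , drop = FALSE])
  list(geneCounts = full, untestable = untestable,
       intergenic = intergenic, retained = retained)
}

# shared permutation machinery ------------------------------------------------

# assignment weight matrix: one row per permutation, entries 1/n1 for the
# "condition" arm and -1/n2 for the "control" arm; first row = observed
.permWeights <- function(n, n1, n_perm, force_sample = FALSE) {
  n2 <- n - n1
  n_comb <- choose(n, n1)
  if (n_comb <= n_perm && !force_sample) {
    sel <- combn(n, n1)
    W <- matrix(-1 / n2, ncol(sel), n)
    W[cbind(rep(seq_len(ncol(sel)), each = n1), as.vector(sel))] <- 1 / n1
    # put the observed assignment (first n1 indices) in row 1
    obs <- which(colSums(sel == seq_len(n1)) == n1)[1L]
    if (obs != 1L) W[c(1L, obs), ] <- W[c(obs, 1L), ]
    attr(W, "exhaustive") <- TRUE
  } else {
    W <- matrix(-1 / n2, n_perm, n)
    W[1L, seq_len(n1)] <- 1 / n1  # observed
    sel <- vapply(seq_len(n_perm - 1L), function(i) sample.int(n, n1),
                  integer(n1))
    W[cbind(rep(2:n_perm, each = n1), as.vector(sel))] <- 1 / n1
    attr(W, "exhaustive") <- FALSE
  }
  W
}

# two-sided permutation p-values for an obs x genes matrix X whose first n1
# rows are the condition arm; one p per column
.permPvalues <- function(X, n1, n_perm, chunk = 400L, force_sample = FALSE) {
  n <- nrow(X)
  W <- .permWeights(n, n1, n_perm, force_sample = force_sample)
  m <- nrow(W)
  G <- ncol(X)
  p <- numeric(G)
  for (s in seq(1L, G, by = chunk)) {
    e <- min(s + chunk - 1L, G)
    stats <- W %*% X[, s:e, drop = FALSE]
    obs <- abs(stats[1L, ])
    tol <- 1e-12 * (1 + obs)
    cmp <- abs(stats) >= matrix(obs - tol, m, e - s + 1L, byrow = TRUE)
    p[s:e] <- colSums(cmp) / m
  }
  list(p = pmax(p, 1 / m), exhaustive = attr(W, "exhaustive"), n_used = m)
}

#' Permutation resampling test for one gene
#'
#' Tests whether a gene's normalized insertion counts differ between two
#' arms. The statistic is the difference of per-arm means; the two-sided
#' p-value is the fraction of label permutations whose absolute statistic
#' is at least the observed one (the observed arrangement counts in both
#' numerator and denominator, so p is floored at 1/n_perm). When the number
#' of distinct assignments is at most \code{n_perm} the enumeration is
#' exhaustive and the p-value deterministic. The fold change is
#' \code{log2((mean_cond + 1) / (mean_ctrl + 1))} (pseudocount 1).
#'
#' @param cond normalized counts in the treatment arm.
#' @param ctrl normalized counts in the control arm.
#' @param n_perm number of permutations, default 20000 (minimum 1000).
#' @param seed optional integer seed for the sampled case.
#' @param method \code{"auto"} switches to exhaustive enumeration whenever
#'   the number of distinct assignments fits within \code{n_perm};
#'   \code{"sample"} always draws random permutations.
#' @return list with \code{log2fc}, \code{p}, \code{exhaustive},
#'   \code{n_perm_used}.
#' @export
resamplingTest <- function(cond, ctrl, n_perm = 20000L, seed = NULL,
                           method = c("auto", "sample")) {
  method <- match.arg(method)
  .stopIfNot(length(cond) >= 1L && length(ctrl) >= 1L,
             "both arms must be non-empty")
  .stopIfNot(length(cond) + length(ctrl) >= 2L, "need >= 2 observations")
  .stopIfNot(n_perm >= 1000L, "n_perm must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(c(cond, ctrl), ncol = 1L)
  res <- .permPvalues(X, length(cond), n_perm,
                      force_sample = method == "sample")
  list(log2fc = log2((mean(cond) + 1) / (mean(ctrl) + 1)),
       p = res$p, exhaustive = res$exhaustive, n_perm_used = res$n_used)
}

#' Doublings-bias correction of a fitness fold change
#'
#' Rescales a log2 fold change to the control arm's doubling count:
#' \code{log2fc * G_ctrl / G_cond}, so abundance changes driven purely by
#' different overall growth extents are deflated. Nonpositive doubling
#' counts leave the value uncorrected and flagged.
#'
#' @param log2fc log2 fold change(s).
#' @param G_cond,G_ctrl population doublings in the two arms.
#' @return list with \code{log2fc_corrected} and logical \code{corrected}.
#' @export
doublingsCorrect <- function(log2fc, G_cond, G_ctrl) {
  ok <- is.finite(G_cond) & is.finite(G_ctrl) & G_cond > 0 & G_ctrl > 0
  out <- log2fc
  out[ok] <- log2fc[ok] * (G_ctrl[ok] / G_cond[ok])
  if (!all(ok)) warning("nonpositive doublings; correction skipped for ",
                        sum(!ok), " value(s)")
  list(log2fc_corrected = out, corrected = ok)
}

#' Flag significant gene fitness hits
#'
#' Applies the significance rule for pooled-library fitness effects:
#' \code{p_adj < alpha} and \code{|log2fc| > lfc_min}, and records the
#' effect direction.
#'
#' @param results data.frame with columns \code{p_adj} and \code{log2fc}.
#' @param alpha adjusted-p threshold, default 0.05.
#' @param lfc_min absolute log2 fold-change threshold, default 0.25.
#' @return \code{results} with added \code{is_hit} and \code{direction}.
#' @export
callGeneHits <- function(results, alpha = 0.05, lfc_min = 0.25) {
  results$is_hit <- !is.na(results$p_adj) & results$p_adj < alpha &
    abs(results$log2fc) > lfc_min
  results$direction <- ifelse(results$log2fc > 0, "enriched", "depleted")
  results
}

#' Gene-set enrichment among fitness hits
#'
#' Per functional term, a one-sided (greater) Fisher exact test on the 2x2
#' table of hit/non-hit by in-term/not-in-term genes, BH-corrected across
#' terms. Terms without background genes are skipped.
#'
#' @param hit_genes character vector of hit gene ids (subset of background).
#' @param background character vector of all testable gene ids.
#' @param term_map named list mapping gene id to a character vector of term
#'   ids.
#' @return data.frame with per-term contingency counts, \code{p} and
#'   \code{p_adj}.
#' @export
termEnrichment <- function(hit_genes, background, term_map) {
  .stopIfNot(all(hit_genes %in% background),
             "hit_genes must be a subset of background")
  term_map <- term_map[names(term_map) %in% background]
  terms <- unique(unlist(term_map, use.names = FALSE))
  if (length(terms) == 0L) return(NULL)
  n_tot <- length(background)
  n_hit <- length(hit_genes)
  res <- lapply(terms, function(tm) {
    in_term <- names(term_map)[vapply(term_map, function(x) tm %in% x,
                                      logical(1))]
    k <- length(in_term)
    if (k == 0L) return(NULL)
    a <- sum(hit_genes %in% in_term)            # hits in term
    tab <- matrix(c(a, k - a, n_hit - a, n_tot - k - (n_hit - a)), 2L)
    data.frame(term_id = tm, n_hits_in_term = a, n_hits_total = n_hit,
               n_genes_in_term = k, n_genes_total = n_tot,
               p = fisher.test(tab, alternative = "greater")$p.value)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bhAdjust(res$p)
  rownames(res) <- NULL
  res
}

#' Full pooled-library fitness pipeline
#'
#' For one treatment condition against a control: TTR-normalizes the count
#' matrix, masks insertion sites outside the central 80 percent of coding
#' regions, and tests each gene by permutation resampling on its site-level
#' observations (every retained site in every sample of an arm is one
#' observation, the convention of transposon resampling tools), followed by
#' BH correction, the doublings-bias correction and hit flagging. Genes with
#' no retained site are reported untestable.
#'
#' @param ie an \linkS4class{InsertionExperiment}.
#' @param geneTable data.frame with \code{gene_id}, \code{start}, \code{end},
#'   \code{strand}.
#' @param condition condition label of the treatment arm.
#' @param control condition label of the control arm.
#' @param n_perm permutations per gene, default 20000.
#' @param seed optional integer seed.
#' @param alpha,lfc_min hit thresholds (defaults 0.05, 0.25).
#' @return list with \code{results} (per-gene data.frame: means, log2fc,
#'   corrected log2fc, p, p_adj, is_hit, direction) and \code{untestable}.
#' @export
tnseqFit <- function(ie, geneTable, condition, control, n_perm = 20000L,
                     seed = NULL, alpha = 0.05, lfc_min = 0.25) {
  .stopIfNot(is(ie, "InsertionExperiment"), "ie must be an InsertionExperiment")
  if (!is.null(seed)) set.seed(seed)
  cd <- colData(ie)
  cond_s <- which(cd$condition == condition)
  ctrl_s <- which(cd$condition == control)
  .stopIfNot(length(cond_s) >= 1L && length(ctrl_s) >= 1L,
             "both condition arms must have samples")
  norm <- ttrNormalize(assay(ie, "counts"))$normalized
  sites <- as.data.frame(rowData(ie))
  agg <- geneAggregate(norm, sites, geneTable)
  testable <- setdiff(geneTable$gene_id, agg$untestable)
  gidx <- match(sites$gene_id, geneTable$gene_id)
  site_gene <- ifelse(agg$retained, sites$gene_id, NA_character_)

  # per-gene site-level observation matrix, grouped by site count so genes
  # with equal design share one permutation enumeration
  sites_by_gene <- split(seq_len(nrow(norm))[agg$retained],
                         factor(site_gene[agg$retained], levels = testable))
  n_sites <- lengths(sites_by_gene)
  p <- setNames(rep(NA_real_, length(testable)), testable)
  for (k in sort(unique(n_sites))) {
    genes_k <- names(n_sites)[n_sites == k]
    n1 <- k * length(cond_s)
    n2 <- k * length(ctrl_s)
    X <- vapply(genes_k, function(g) {
      rows <- sites_by_gene[[g]]
      c(as.vector(norm[rows, cond_s, drop = FALSE]),
        as.vector(norm[rows, ctrl_s, drop = FALSE]))
    }, numeric(n1 + n2))
    X <- matrix(X, nrow = n1 + n2)
    p[genes_k] <- .permPvalues(X, n1, n_perm)$p
  }

  gc <- agg$geneCounts[testable, , drop = FALSE]
  mean_cond <- rowMeans(gc[, cond_s, drop = FALSE])
  mean_ctrl <- rowMeans(gc[, ctrl_s, drop = FALSE])
  log2fc <- log2((mean_cond + 1) / (mean_ctrl + 1))
  G_cond <- mean(cd$doublings[cond_s])
  G_ctrl <- mean(cd$doublings[ctrl_s])
  corr <- doublingsCorrect(log2fc, rep(G_cond, length(log2fc)),
                           rep(G_ctrl, length(log2fc)))
  res <- data.frame(gene_id = testable, n_sites = as.integer(n_sites[testable]),
                    mean_ctrl = mean_ctrl, mean_cond = mean_cond,
                    log2fc = log2fc,
                    log2fc_corrected = corr$log2fc_corrected,
                    p = unname(p))
  res$p_adj <- bhAdjust(res$p)
  res <- callGeneHits(res, alpha = alpha, lfc_min = lfc_min)
  rownames(res) <- NULL
  list(results = res, untestable = agg$untestable)
}
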