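#' Differential expression by log2 fold-change threshold
#'
#' For every transcript, `log2FC = log2((FPKM_a + pseudocount) /
#' (FPKM_b + pseudocount))`; a transcript is called up in A when
#' `log2FC > threshold`, up in B when `log2FC < -threshold`, otherwise not
#' differentially expressed (strict inequality, so
#' `|log2FC| > threshold <=> direction != not_DE`). The pseudocount guards
#' against zero FPKM.
#'
#' @param expr Expression matrix (see [read_expression()]).
#' @param sample_a,sample_b Column names to compare.
#' @param log2fc_threshold Threshold on `|log2FC|` (default 0.6).
#' @param pseudocount Added to both FPKM values (default 1).
#' @return A `diff_result` data.table with columns `id`, `log2fc`,
#'   `direction` (`up_in_A`/`up_in_B`/`not_DE`); parameters stored as
#'   attributes.
#' @export
differential_expression <- function(expr, sample_a, sample_b,
                                    log2fc_threshold = 0.6, pseudocount = 1) {
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(expr)) stop("sample '", s, "' not in matrix")
  lfc <- log2((expr[, sample_a] + pseudocount) /
                (expr[, sample_b] + pseudocount))
  dir <- ifelse(lfc > log2fc_threshold, "up_in_A",
         ifelse(lfc < -log2fc_threshold, "up_in_B", "not_DE"))
  out <- data.table(id = rownames(expr), log2fc = unname(lfc),
                    direction = unname(dir))
  structure(out, class = c("diff_result", class(out)),
            log2fc_threshold = log2fc_threshold, pseudocount = pseudocount,
            sample_a = sample_a, sample_b = sample_b)
}

#' Genes carrying differential peaks
#'
#' Maps externally computed differential histone-mark regions (e.g. from a
#' two-condition peak caller) to genes with the same rule as
#' [associate_peaks_to_genes()]: gene body plus `upstream_bp` upstream of
#' the TSS, strand-aware.
#'
#' @param diff_regions A `peak_set` of differential regions.
#' @param ann An [annotation()].
#' @param upstream_bp Upstream window in bp (default 2000).
#' @return Sorted character vector of gene ids.
#' @export
genes_with_differential_peaks <- function(diff_regions, ann,
                                          upstream_bp = 2000) {
  associate_peaks_to_genes(diff_regions, ann, upstream_bp)$genes
}

#' Overlap counts between two gene sets
#'
#' @param genes_a,genes_b Character vectors (duplicates ignored).
#' @param label_a,label_b Labels for reporting.
#' @return List with `n_common`, `n_a_only`, `n_b_only`, `label_a`,
#'   `label_b` — the three counts of a two-set Venn diagram.
#' @export
overlap_sets <- function(genes_a, genes_b, label_a = "A", label_b = "B") {
  a <- unique(genes_a); b <- unique(genes_b)
  list(n_common = length(intersect(a, b)),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)),
       label_a = label_a, label_b = label_b)
}

# squared Euclidean distances rows of x vs rows of centers
.sqdist <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
}

# k-means++ seeding (deterministic given the RNG state)
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(.sqdist(x, centers[seq_len(j - 1L), , drop = FALSE]), 1L, min)
    d2 <- pmax(d2, 0)
    pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j, ] <- x[pick, ]
  }
  centers
}

#' Cluster TSS-flanking signal profiles
#'
#' k-means (Lloyd iterations, k-means++ seeding) on per-row max-normalized
#' signal vectors around the TSS. Rows with all-zero signal cannot be
#' max-normalized and are pre-assigned to a dedicated zero cluster (cluster
#' 0). Iteration stops at assignment convergence or `max_iter` rounds; the
#' within-cluster sum of squares is non-increasing over iterations and the
#' result is deterministic given `seed`. Empty clusters keep their previous
#' center. Assignment ties go to the lowest-index center.
#'
#' @param signal_matrix Numeric matrix, genes x bins, finite.
#' @param k Number of clusters among non-zero rows (default 6).
#' @param seed RNG seed controlling the seeding.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @return List with `cluster` (named integer vector; 0 = zero-signal rows),
#'   `centers`, `wss_trace` (total within-cluster SS after each assignment
#'   step) and `iterations`.
#' @export
cluster_tss_signal <- function(signal_matrix, k = 6, seed = 1,
                               max_iter = 300) {
  m <- as.matrix(signal_matrix)
  if (!all(is.finite(m))) stop("signal matrix must be finite")
  rmax <- apply(m, 1L, max)
  zero <- rmax == 0
  x <- m[!zero, , drop = FALSE] / rmax[!zero]
  if (k > nrow(x))
    stop("k = ", k, " exceeds the ", nrow(x), " rows with non-zero signal")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  centers <- .kmeanspp_init(x, k)
  assign_vec <- rep(0L, nrow(x))
  wss_trace <- numeric()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .sqdist(x, centers)
    newassign <- max.col(-d2, ties.method = "first")
    wss_trace <- c(wss_trace,
                   sum(d2[cbind(seq_len(nrow(x)), newassign)]))
    if (identical(newassign, assign_vec) || iter >= max_iter) {
      assign_vec <- newassign
      break
    }
    assign_vec <- newassign
    for (j in seq_len(k)) {
      rows <- assign_vec == j
      if (any(rows)) centers[j, ] <- colMeans(x[rows, , drop = FALSE])
    }
  }
  cluster <- rep(0L, nrow(m))
  cluster[!zero] <- assign_vec
  names(cluster) <- rownames(m)
  list(cluster = cluster, centers = centers, wss_trace = wss_trace,
       iterations = iter)
}

#' Hierarchical ordering of an expression matrix
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' transformed rows (default `log2(x + 1)`), as used to order transcripts in
#' expression heatmaps. Rows are pre-sorted by id so the leaf order is
#' deterministic and invariant to input row permutation.
#'
#' @param expr Numeric matrix with row names.
#' @param transform Function applied to the matrix before clustering.
#' @return List with `order` (row ids in leaf order), `heights` (merge
#'   heights) and the underlying `hclust` object.
#' @export
hierarchical_order <- function(expr, transform = function(x) log2(x + 1)) {
  m <- as.matrix(expr)
  if (nrow(m) < 2L) stop("need >= 2 rows")
  m <- transform(m)
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "average")
  list(order = rownames(m)[hc$order], heights = hc$height, hclust = hc)
}
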