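REGION_CLASSES <- c("promoter", "utr5", "utr3", "coding_exon", "intron",
                    "intergenic")
# per-base label priority, low -> high (painted in this order)
.PRIORITY <- c("promoter", "intron", "utr3", "utr5", "coding_exon")

.empty_iv <- function() data.table(chrom = character(), start = numeric(),
                                   end = numeric())
.rbl <- function(l) if (length(l)) rbindlist(l) else .empty_iv()

# Per-class raw interval lists (0-based half-open) for one annotation.
region_class_intervals <- function(ann, promoter_bp) {
  coding <- list(); utr5 <- list(); utr3 <- list(); intron <- list()
  for (tx in ann$transcripts) {
    ex <- tx$exons
    if (is.null(tx$cds)) {
      coding[[length(coding) + 1L]] <- data.table(chrom = tx$chrom,
                                                  start = ex$start,
                                                  end = ex$end)
    } else {
      a <- tx$cds[1L]; b <- tx$cds[2L]
      cs <- pmax(ex$start, a); ce <- pmin(ex$end, b)
      keep <- ce > cs
      if (any(keep))
        coding[[length(coding) + 1L]] <- data.table(chrom = tx$chrom,
                                                    start = cs[keep],
                                                    end = ce[keep])
      # exonic bases before/after the CDS; which is 5' depends on strand
      ls <- ex$start; le <- pmin(ex$end, a); lkeep <- le > ls
      rs <- pmax(ex$start, b); re <- ex$end; rkeep <- re > rs
      left <- data.table(chrom = tx$chrom, start = ls[lkeep], end = le[lkeep])
      right <- data.table(chrom = tx$chrom, start = rs[rkeep], end = re[rkeep])
      if (tx$strand == "-") {
        if (nrow(right)) utr5[[length(utr5) + 1L]] <- right
        if (nrow(left)) utr3[[length(utr3) + 1L]] <- left
      } else {
        if (nrow(left)) utr5[[length(utr5) + 1L]] <- left
        if (nrow(right)) utr3[[length(utr3) + 1L]] <- right
      }
    }
    if (nrow(ex) > 1L)
      intron[[length(intron) + 1L]] <- data.table(chrom = tx$chrom,
                                                  start = ex$end[-nrow(ex)],
                                                  end = ex$start[-1L])
  }
  g <- ann$gene_table
  promoter <- if (nrow(g)) {
    ps <- ifelse(g$strand == "-", g$tss, g$tss - promoter_bp)
    pe <- ifelse(g$strand == "-", g$tss + promoter_bp, g$tss)
    ps <- pmax(ps, 0)
    pe <- pmin(pe, ann$chrom_sizes[g$chrom])
    data.table(chrom = g$chrom, start = ps, end = pe)[end > start]
  } else .empty_iv()
  list(promoter = promoter,
       intron = .rbl(intron),
       utr3 = .rbl(utr3),
       utr5 = .rbl(utr5),
       coding_exon = .rbl(coding))
}

#' Partition the genome into six regional classes
#'
#' Labels every base of every chromosome with exactly one of: promoter,
#' 5' UTR, 3' UTR, coding exon, intron, intergenic. Where classes overlap, a
#' base takes the highest-priority label, with priority
#' `coding_exon > utr5 > utr3 > intron > promoter > intergenic`, so a base
#' inside one gene's intron and another gene's promoter stays genic. UTRs are
#' derived as exon-minus-CDS on the strand-appropriate side of the coding
#' interval; transcripts without a CDS contribute their exons to
#' `coding_exon`. The promoter is `promoter_bp` upstream of each gene TSS
#' (strand-aware, clipped at chromosome bounds).
#'
#' @param ann An [annotation()].
#' @param promoter_bp Promoter width in bp upstream of the TSS (default 2000,
#'   matching the peak-to-gene association window).
#' @return A `region_partition`: data.table with columns `chrom`, `start`,
#'   `end`, `label` tiling every chromosome exactly once, with attribute
#'   `promoter_bp` and `chrom_sizes`.
#' @export
build_region_partition <- function(ann, promoter_bp = 2000) {
  cls <- region_class_intervals(ann, promoter_bp)
  runs <- list()
  for (cm in names(ann$chrom_sizes)) {
    len <- ann$chrom_sizes[[cm]]
    sub <- lapply(cls, function(dt) {
      dt <- dt[chrom == cm]
      IRanges::IRanges(dt$start + 1L, dt$end)
    })
    bins <- IRanges::disjoin(c(IRanges::IRanges(1L, len),
                               do.call(c, unname(sub))))
    lab <- rep("intergenic", length(bins))
    for (cl in .PRIORITY)
      lab[IRanges::overlapsAny(bins, sub[[cl]])] <- cl
    dt <- data.table(chrom = cm, start = IRanges::start(bins) - 1,
                     end = IRanges::end(bins), label = lab)
    # coalesce consecutive runs with the same label
    dt[, grp := cumsum(c(TRUE, lab[-1L] != lab[-length(lab)]))]
    dt <- dt[, .(chrom = chrom[1L], start = start[1L], end = end[.N],
                 label = label[1L]), by = grp][, grp := NULL]
    runs[[cm]] <- dt
  }
  part <- rbindlist(runs)
  structure(part, class = c("region_partition", class(part)),
            promoter_bp = promoter_bp, chrom_sizes = ann$chrom_sizes)
}

#' Genome fraction of each regional class
#'
#' @param partition A `region_partition`.
#' @return Named numeric vector (percent of genome per class, all six
#'   classes, summing to 100).
#' @export
region_fractions <- function(partition) {
  bp <- as.data.table(partition)[, sum(end - start), by = label]
  out <- stats::setNames(rep(0, length(REGION_CLASSES)), REGION_CLASSES)
  out[bp$label] <- bp$V1
  100 * out / sum(out)
}

#' Distribution of peak base pairs across regional classes
#'
#' Each peak's bases are apportioned to the classes covering them
#' (bp-weighted, not one-class-per-peak), and percentages are taken over the
#' total peak bp, so the six classes sum to 100. Peaks extending beyond
#' chromosome bounds are clipped with a warning.
#'
#' @param peaks A `peak_set`.
#' @param partition A `region_partition`.
#' @return Named numeric vector (percent of peak bp per class).
#' @export
peak_region_distribution <- function(peaks, partition) {
  sizes <- attr(partition, "chrom_sizes")
  pk <- as.data.table(peaks)[, .(chrom, start, end)]
  unknown <- !pk$chrom %in% names(sizes)
  if (any(unknown)) {
    warning(sum(unknown), " peak(s) on chromosomes absent from the partition",
            " were dropped")
    pk <- pk[!unknown]
  }
  clipped <- pk$start < 0 | pk$end > sizes[pk$chrom]
  if (any(clipped)) {
    warning(sum(clipped), " peak(s) clipped to chromosome bounds")
    pk[, `:=`(start = pmax(start, 0), end = pmin(end, sizes[chrom]))]
    pk <- pk[end > start]
  }
  part <- as.data.table(partition)
  bp <- stats::setNames(rep(0, length(REGION_CLASSES)), REGION_CLASSES)
  for (cm in unique(pk$chrom)) {
    p <- pk[chrom == cm]; r <- part[chrom == cm]
    h <- IRanges::findOverlaps(IRanges::IRanges(p$start + 1L, p$end),
                               IRanges::IRanges(r$start + 1L, r$end))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    w <- pmin(p$end[qi], r$end[si]) - pmax(p$start[qi], r$start[si])
    agg <- data.table(label = r$label[si], w = w)[, sum(w), by = label]
    bp[agg$label] <- bp[agg$label] + agg$V1
  }
  if (sum(bp) == 0) stop("no peak bases overlap the partition")
  100 * bp / sum(bp)
}

#' Associate peaks with genes via gene body plus upstream window
#'
#' A gene is associated iff some peak overlaps, by >= 1 bp, the interval
#' from `upstream_bp` upstream of its TSS (strand-aware) through the end of
#' its span: `[TSS - upstream_bp, span end)` for forward genes,
#' `[span start, TSS + upstream_bp)` for reverse genes. A peak may associate
#' with multiple genes. Genes of unknown strand are treated as forward.
#'
#' @param peaks A `peak_set`.
#' @param ann An [annotation()].
#' @param upstream_bp Upstream window in bp (default 2000).
#' @return List with `pairs` (data.table of gene/peak name pairs), `genes`
#'   (sorted associated gene ids) and `n_genes`.
#' @export
associate_peaks_to_genes <- function(peaks, ann, upstream_bp = 2000) {
  g <- copy(ann$gene_table)
  if (nrow(g) == 0L)
    return(list(pairs = data.table(gene = character(), peak = character()),
                genes = character(), n_genes = 0L))
  g[, `:=`(wstart = ifelse(strand == "-", start, pmax(tss - upstream_bp, 0)),
           wend = ifelse(strand == "-", tss + upstream_bp, end))]
  pk <- as.data.table(peaks)
  pairs <- list()
  for (cm in intersect(unique(g$chrom), unique(pk$chrom))) {
    gs <- g[chrom == cm]; p <- pk[chrom == cm]
    h <- IRanges::findOverlaps(IRanges::IRanges(gs$wstart + 1L, gs$wend),
                               IRanges::IRanges(p$start + 1L, p$end))
    if (length(h))
      pairs[[cm]] <- data.table(gene = gs$gene[S4Vectors::queryHits(h)],
                                peak = p$name[S4Vectors::subjectHits(h)])
  }
  pairs <- if (length(pairs)) rbindlist(pairs) else
    data.table(gene = character(), peak = character())
  setorder(pairs, gene, peak)
  genes <- sort(unique(pairs$gene))
  list(pairs = pairs, genes = genes, n_genes = length(genes))
}

#' Depth-normalize a coverage track to per-million mapped reads
#'
#' Divides every run value by `mapped_reads / 1e6`, the standard
#' reads-per-million scaling of ChIP-seq wiggle tracks. Normalizing an
#' already-normalized track is an error.
#'
#' @param track A raw `coverage_track`.
#' @param mapped_reads Total mapped reads of the library (`> 0`).
#' @return The normalized `coverage_track`
#'   (`normalization_state = "per-million"`).
#' @export
normalize_per_million <- function(track, mapped_reads) {
  if (!identical(attr(track, "normalization_state"), "raw"))
    stop("track is already normalized")
  if (!is.numeric(mapped_reads) || mapped_reads <= 0)
    stop("mapped_reads must be positive")
  out <- copy(as.data.table(track))
  out[, value := value / (mapped_reads / 1e6)]
  structure(out, class = c("coverage_track", class(out)),
            normalization_state = "per-million")
}

# mean coverage per bin given ascending bin edges on one chromosome
.bin_means <- function(sub, edges) {
  Fv <- coverage_integral(sub, edges)
  diff(Fv) / diff(edges)
}

#' Meta-gene coverage profile
#'
#' Averages a coverage track over a gene set after rescaling every gene body
#' to `body_bins` bins, with fixed-width flanking bins on either side.
#' Reverse-strand genes are flipped so bin 1 is always the 5'-most upstream
#' bin. Bin values are exact means of the stepwise track (fractional bases
#' for bodies shorter than `body_bins`); bases beyond chromosome bounds
#' contribute 0 signal.
#'
#' @param track A `coverage_track`.
#' @param genes An [annotation()] or data.frame with columns `chrom`,
#'   `start`, `end`, `strand`.
#' @param flank_bp Flank width in bp on each side (default 1000).
#' @param body_bins Number of body bins (default 100).
#' @param flank_bin_bp Width of each flank bin in bp (default 50;
#'   `flank_bp` must be a multiple).
#' @return A `metagene_profile`: list with `values` (mean per bin),
#'   `n_genes`, `flank_bins`, `body_bins`, `flank_bp`, `flank_bin_bp`.
#' @export
metagene_profile <- function(track, genes, flank_bp = 1000, body_bins = 100,
                             flank_bin_bp = 50) {
  if (flank_bp %% flank_bin_bp != 0)
    stop("flank_bp must be a multiple of flank_bin_bp")
  nfl <- flank_bp / flank_bin_bp
  g <- if (inherits(genes, "annotation")) genes$gene_table else
    as.data.table(genes)
  if (nrow(g) == 0L) stop("genes must be non-empty")
  if (!"strand" %in% names(g)) g$strand <- "+"
  trk <- as.data.table(track)
  nbins <- nfl + body_bins + nfl
  acc <- matrix(0, nrow(g), nbins)
  bychrom <- split(seq_len(nrow(g)), g$chrom)
  for (cm in names(bychrom)) {
    sub <- trk[chrom == cm]
    setorder(sub, start)
    for (i in bychrom[[cm]]) {
      s <- g$start[i]; e <- g$end[i]
      edges <- c(seq(s - flank_bp, s, by = flank_bin_bp),
                 s + (e - s) * seq_len(body_bins - 1L) / body_bins,
                 seq(e, e + flank_bp, by = flank_bin_bp))
      v <- .bin_means(sub, edges)
      if (g$strand[i] == "-") v <- rev(v)
      acc[i, ] <- v
    }
  }
  structure(list(values = colMeans(acc), n_genes = nrow(g),
                 flank_bins = nfl, body_bins = body_bins,
                 flank_bp = flank_bp, flank_bin_bp = flank_bin_bp),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d genes, %d+%d+%d bins\n", x$n_genes,
              x$flank_bins, x$body_bins, x$flank_bins))
  invisible(x)
}

#' Meta-gene profiles stratified by expression quantile
#'
#' Genes with FPKM > 0 in the chosen sample are ranked (ascending; FPKM ties
#' broken by gene id) and cut into `n_quantiles` equal-count groups, any
#' remainder going to the lowest-expression groups; genes with FPKM = 0 form
#' a separate not-expressed group. One [metagene_profile()] is computed per
#' group. Genes absent from the matrix count as FPKM = 0.
#'
#' @param track A `coverage_track`.
#' @param genes An [annotation()].
#' @param expr Expression matrix (see [read_expression()]), rows keyed by
#'   gene/transcript id.
#' @param sample Column of `expr` to stratify on.
#' @param n_quantiles Number of expressed-gene groups (default 9).
#' @inheritParams metagene_profile
#' @return List with `profiles` (named `Q1`..`Qn`, lowest expression first;
#'   empty groups are `NULL`), `not_expressed`, `sizes` and `membership`
#'   (named list of gene ids per group).
#' @export
profiles_by_expression_quantile <- function(track, genes, expr, sample,
                                            n_quantiles = 9,
                                            flank_bp = 1000, body_bins = 100,
                                            flank_bin_bp = 50) {
  if (!sample %in% colnames(expr)) stop("sample '", sample, "' not in matrix")
  g <- genes$gene_table
  fpkm <- stats::setNames(rep(0, nrow(g)), g$gene)
  in_mat <- intersect(g$gene, rownames(expr))
  fpkm[in_mat] <- expr[in_mat, sample]
  expressed <- names(fpkm)[fpkm > 0]
  expressed <- expressed[order(fpkm[expressed], expressed)]
  n <- length(expressed)
  base <- n %/% n_quantiles
  sizes <- rep(base, n_quantiles)
  extra <- n %% n_quantiles
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  upper <- cumsum(sizes)
  lower <- c(0, upper[-n_quantiles]) + 1L
  membership <- lapply(seq_len(n_quantiles), function(q)
    if (sizes[q] > 0L) expressed[lower[q]:upper[q]] else character())
  names(membership) <- paste0("Q", seq_len(n_quantiles))
  prof_of <- function(ids) {
    if (length(ids) == 0L) return(NULL)
    metagene_profile(track, g[g$gene %in% ids],
                     flank_bp = flank_bp, body_bins = body_bins,
                     flank_bin_bp = flank_bin_bp)
  }
  profiles <- lapply(membership, prof_of)
  ne_ids <- names(fpkm)[fpkm == 0]
  list(profiles = profiles,
       not_expressed = prof_of(ne_ids),
       sizes = stats::setNames(sizes, names(membership)),
       membership = c(membership, list(not_expressed = ne_ids)))
}
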