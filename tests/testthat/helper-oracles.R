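# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's interval machinery: overlaps
# are computed on explicit per-base sets, components with igraph, partitions
# by painting a per-base vector.

# per-base overlap of two half-open intervals
o_interval_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L)))
}

# per-base exonic overlap of two transcript models
o_exonic_overlap <- function(t1, t2) {
  if (t1$chrom != t2$chrom) return(0L)
  b1 <- unlist(mapply(seq.int, t1$exons$start, t1$exons$end - 1L,
                      SIMPLIFY = FALSE))
  b2 <- unlist(mapply(seq.int, t2$exons$start, t2$exons$end - 1L,
                      SIMPLIFY = FALSE))
  length(intersect(b1, b2))
}

# per-base six-class labeling of one annotation; returns a list of per-base
# character vectors, one per chromosome (painted in increasing priority)
o_partition_bases <- function(ann, promoter_bp = 2000) {
  ivs <- list(promoter = list(), intron = list(), utr3 = list(),
              utr5 = list(), coding_exon = list())
  add <- function(cl, chrom, s, e)
    ivs[[cl]][[length(ivs[[cl]]) + 1L]] <<- list(chrom, s, e)
  for (g in ann$genes) {
    if (g$strand == "-") add("promoter", g$chrom, g$tss, g$tss + promoter_bp)
    else add("promoter", g$chrom, g$tss - promoter_bp, g$tss)
  }
  for (tx in ann$transcripts) {
    ex <- tx$exons
    if (nrow(ex) > 1L) for (j in 2:nrow(ex))
      add("intron", tx$chrom, ex$end[j - 1L], ex$start[j])
    if (is.null(tx$cds)) {
      for (j in seq_len(nrow(ex)))
        add("coding_exon", tx$chrom, ex$start[j], ex$end[j])
    } else {
      a <- tx$cds[1L]; b <- tx$cds[2L]
      for (j in seq_len(nrow(ex))) {
        left <- c(ex$start[j], min(ex$end[j], a))
        mid <- c(max(ex$start[j], a), min(ex$end[j], b))
        right <- c(max(ex$start[j], b), ex$end[j])
        add(if (tx$strand == "-") "utr3" else "utr5", tx$chrom,
            left[1L], left[2L])
        add("coding_exon", tx$chrom, mid[1L], mid[2L])
        add(if (tx$strand == "-") "utr5" else "utr3", tx$chrom,
            right[1L], right[2L])
      }
    }
  }
  out <- list()
  for (cm in names(ann$chrom_sizes)) {
    len <- ann$chrom_sizes[[cm]]
    v <- rep("intergenic", len)
    for (cl in c("promoter", "intron", "utr3", "utr5", "coding_exon"))
      for (iv in ivs[[cl]]) {
        if (iv[[1L]] != cm) next
        s <- max(iv[[2L]], 0); e <- min(iv[[3L]], len)
        if (e > s) v[(s + 1L):e] <- cl
      }
    out[[cm]] <- v
  }
  out
}

# expand a region_partition to per-base labels per chromosome
expand_partition <- function(part) {
  dt <- data.table::as.data.table(part)
  lapply(split(dt, dt$chrom), function(sub) {
    sub <- sub[order(sub$start)]
    rep(sub$label, sub$end - sub$start)
  })
}

# igraph-based single-linkage components over exonic overlap (no strand
# conflicts expected in the instances this is applied to)
o_merge_members <- function(txs) {
  n <- length(txs)
  chrom <- vapply(txs, `[[`, "", "chrom")
  s <- vapply(txs, function(t) t$exons$start[1L], 0)
  e <- vapply(txs, function(t) t$exons$end[nrow(t$exons)], 0)
  # span overlap is necessary for exonic overlap; prefilter the pairs
  cand <- which(outer(chrom, chrom, `==`) &
                  outer(s, e, `<`) & outer(e, s, `>`) &
                  outer(seq_len(n), seq_len(n), `<`), arr.ind = TRUE)
  edges <- integer()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (exonic_overlap_bp(txs[[i]], txs[[j]]) >= 1)
      edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  ids <- vapply(txs, `[[`, "", "id")
  unname(lapply(split(ids, comp), function(m) sort(m)))
}

# canonical form of a set of member-id sets, for comparison
canon_members <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, "", collapse = ","))]
}

# random transcript on one of a few chromosomes
rand_tx <- function(id, chroms = c("chr1", "chr2"), max_pos = 50000,
                    max_exons = 3, strand = "*") {
  n_ex <- sample.int(max_exons, 1L)
  s <- sample.int(max_pos, 1L)
  exons <- data.frame(start = numeric(), end = numeric())
  pos <- s
  for (k in seq_len(n_ex)) {
    w <- sample(50:500, 1L)
    exons <- rbind(exons, data.frame(start = pos, end = pos + w))
    pos <- pos + w + sample(20:400, 1L)
  }
  transcript_model(id, sample(chroms, 1L), exons, strand = strand)
}

# the worked single-gene toy annotation: 10-kb chromosome, forward gene
# [2000,5000) with exons [2000,2600)+[4000,5000) and CDS [2200,4500)
toy_annotation <- function() {
  tx <- transcript_model("g1.t1", "chr1",
                         data.frame(start = c(2000, 4000),
                                    end = c(2600, 5000)),
                         strand = "+", cds = c(2200, 4500))
  annotation(list(gene_model("g1", list(tx))), c(chr1 = 10000))
}

# random toy annotation for partition fuzzing: non-overlapping genes with
# varying exon counts, strands, and optional CDS
rand_annotation <- function(n_genes = 10, chrom_len = 50000,
                            chroms = c("chrA", "chrB")) {
  sizes <- stats::setNames(rep(chrom_len, length(chroms)), chroms)
  genes <- list()
  pos <- stats::setNames(rep(100, length(chroms)), chroms)
  for (i in seq_len(n_genes)) {
    cm <- sample(chroms, 1L)
    n_ex <- sample.int(4L, 1L)
    start <- pos[[cm]] + sample(200:3000, 1L)
    w <- sample(100:800, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1L) sample(50:600, n_ex - 1L, replace = TRUE) else
      integer()
    starts <- start + cumsum(c(0, w[-n_ex] + gaps))
    exons <- data.frame(start = starts, end = starts + w)
    if (exons$end[n_ex] > chrom_len - 100) next
    pos[[cm]] <- exons$end[n_ex]
    strand <- sample(c("+", "-"), 1L)
    cds <- NULL
    if (stats::runif(1) < 0.7) {
      span <- c(exons$start[1L], exons$end[n_ex])
      u1 <- sample(0:150, 1L); u2 <- sample(0:150, 1L)
      if (span[2L] - u2 > span[1L] + u1)
        cds <- c(span[1L] + u1, span[2L] - u2)
    }
    id <- sprintf("G%03d", i)
    genes[[length(genes) + 1L]] <- gene_model(
      id, list(transcript_model(paste0(id, ".t1"), cm, exons,
                                strand = strand, cds = cds)))
  }
  annotation(genes, sizes)
}

# direct restatement of the peak-center strand rule, for grid checks
o_strand_rule <- function(span_start, span_end, center, max_dist = 2000) {
  dl <- abs(center - span_start)
  dr <- abs(center - span_end)
  if (min(dl, dr) > max_dist) return("*")
  if (dl < dr) "+" else if (dr < dl) "-" else "*"
}

# small peak_set builder
make_peaks <- function(chrom, start, end, center = NULL, tissue = "leaf") {
  dt <- data.table::data.table(
    chrom = chrom, start = start, end = end,
    name = sprintf("pk%02d", seq_along(start)), score = 100,
    center = if (is.null(center)) floor((start + end) / 2) else center)
  data.table::setorder(dt, chrom, start)
  structure(dt, class = c("peak_set", class(dt)), tissue_label = tissue)
}
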