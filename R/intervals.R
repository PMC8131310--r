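#' Genomic interval
#'
#' A single genomic interval in 0-based half-open coordinates, the convention
#' used throughout the package. 1-based inclusive GTF coordinates are
#' converted at the I/O boundary only (see [read_gtf()]).
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp), `>= 0`.
#' @param end 0-based exclusive end (bp), `> start`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr1", 100, 300)
#' interval_length(gi) # 200
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || is.na(chrom)) stop("chrom must be a single string")
  if (is.na(start) || start < 0) stop("start must be >= 0")
  if (is.na(end) || end <= start) stop("end must be > start")
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' Overlap between two genomic intervals in base pairs
#'
#' Half-open interval intersection: adjacent intervals (`a$end == b$start`)
#' overlap by 0 bp, and intervals on different chromosomes never overlap.
#'
#' @param a,b `genomic_interval` objects.
#' @return Integer number of overlapping base pairs (`>= 0`).
#' @examples
#' a <- genomic_interval("chr1", 100, 300)
#' b <- genomic_interval("chr1", 250, 350)
#' interval_overlap_bp(a, b) # 50
#' @export
interval_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Transcript model
#'
#' An exon chain on one chromosome with an optional CDS interval. Exons must
#' be sorted, strictly non-overlapping and non-adjacent (`end[i] < start[i+1]`);
#' adjacency is resolved by coalescing before construction.
#'
#' The transcript span is `[first exon start, last exon end)`; transcript
#' length is the span length (the convention used when comparing novel
#' transcripts to reference transcripts), while `exonic_bp()` gives the summed
#' exon length.
#'
#' @param id Unique transcript identifier.
#' @param chrom Chromosome name.
#' @param exons A data.frame with columns `start`, `end` (0-based half-open).
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param cds Optional numeric `c(start, end)` of the coding interval; must
#'   lie within the span.
#' @param source_samples Character vector of sample ids that contributed the
#'   model (used when merging assemblies).
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- transcript_model("t1", "chr1",
#'                        data.frame(start = c(100, 500), end = c(300, 700)))
#' transcript_length(tx) # 600 (span)
#' exonic_bp(tx)         # 400
#' @export
transcript_model <- function(id, chrom, exons, strand = "*", cds = NULL,
                             source_samples = character()) {
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    stop("exons must have columns 'start' and 'end'")
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  if (nrow(exons) < 1L) stop("transcript '", id, "' must have >= 1 exon")
  if (any(exons$start < 0)) stop("transcript '", id, "': exon start < 0")
  if (any(exons$end <= exons$start))
    stop("transcript '", id, "': exon end must exceed start")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons$start, strictly = TRUE) ||
        any(exons$end[-nrow(exons)] >= exons$start[-1L]))
      stop("transcript '", id,
           "': exons must be sorted and non-overlapping (end[i] < start[i+1])")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    if (length(cds) != 2L || cds[2L] <= cds[1L])
      stop("cds must be c(start, end) with end > start")
    if (cds[1L] < exons$start[1L] || cds[2L] > exons$end[nrow(exons)])
      stop("transcript '", id, "': cds outside transcript span")
  }
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 strand = strand, exons = exons, cds = cds,
                 source_samples = unique(as.character(source_samples))),
            class = "transcript_model")
}

#' @rdname transcript_model
#' @param tx A `transcript_model`.
#' @export
tx_span <- function(tx) {
  genomic_interval(tx$chrom, tx$exons$start[1L], tx$exons$end[nrow(tx$exons)],
                   tx$strand)
}

#' @rdname transcript_model
#' @export
transcript_length <- function(tx) {
  tx$exons$end[nrow(tx$exons)] - tx$exons$start[1L]
}

#' @rdname transcript_model
#' @export
exon_count <- function(tx) nrow(tx$exons)

#' @rdname transcript_model
#' @export
exonic_bp <- function(tx) sum(tx$exons$end - tx$exons$start)

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%g-%g(%s) %d exon(s)\n",
              x$id, x$chrom, x$exons$start[1L], x$exons$end[nrow(x$exons)],
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Exonic overlap between two transcript models in base pairs
#'
#' Sum over exon pairs of the half-open interval intersection; 0 when the
#' transcripts sit on different chromosomes. Strand is ignored.
#'
#' @param t1,t2 `transcript_model` objects.
#' @return Total overlapping exonic base pairs.
#' @export
exonic_overlap_bp <- function(t1, t2) {
  if (t1$chrom != t2$chrom) return(0)
  ov <- outer(t1$exons$end, t2$exons$end, pmin) -
    outer(t1$exons$start, t2$exons$start, pmax)
  sum(pmax(0, ov))
}

#' Gene model
#'
#' One or more transcript models grouped under a gene id. All transcripts
#' must share a chromosome; transcripts with known strand must agree. The
#' gene span is the union span of its transcripts and the TSS is the span
#' start for forward-strand genes and the span end for reverse-strand genes
#' (genes of unknown strand are treated as forward).
#'
#' @param id Gene identifier.
#' @param transcripts List of `transcript_model` objects.
#' @return An object of class `gene_model` with derived fields `chrom`,
#'   `strand`, `start`, `end`, `tss`.
#' @export
gene_model <- function(id, transcripts) {
  if (length(transcripts) < 1L) stop("gene '", id, "' must have >= 1 transcript")
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  if (length(chroms) != 1L)
    stop("gene '", id, "': transcripts on multiple chromosomes")
  strands <- setdiff(unique(vapply(transcripts, `[[`, "", "strand")), "*")
  if (length(strands) > 1L)
    stop("gene '", id, "': transcripts with conflicting strands")
  strand <- if (length(strands) == 1L) strands else "*"
  start <- min(vapply(transcripts, function(t) t$exons$start[1L], 0))
  end <- max(vapply(transcripts, function(t) t$exons$end[nrow(t$exons)], 0))
  structure(list(id = as.character(id), chrom = chroms, strand = strand,
                 transcripts = transcripts, start = start, end = end,
                 tss = if (strand == "-") end else start),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%g-%g(%s) %d transcript(s), TSS %g\n",
              x$id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts), x$tss))
  invisible(x)
}

# Flat exon table for a list of transcript models; one row per exon.
tx_exon_table <- function(transcripts, gene_ids = NULL) {
  if (length(transcripts) == 0L)
    return(data.table(tx = character(), gene = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  n_ex <- vapply(transcripts, function(t) nrow(t$exons), 0L)
  data.table(
    tx = rep(vapply(transcripts, `[[`, "", "id"), n_ex),
    gene = if (is.null(gene_ids)) NA_character_ else rep(gene_ids, n_ex),
    chrom = rep(vapply(transcripts, `[[`, "", "chrom"), n_ex),
    start = unlist(lapply(transcripts, function(t) t$exons$start)),
    end = unlist(lapply(transcripts, function(t) t$exons$end)),
    strand = rep(vapply(transcripts, `[[`, "", "strand"), n_ex)
  )
}

# Flat span table; one row per transcript.
tx_span_table <- function(transcripts, gene_ids = NULL) {
  if (length(transcripts) == 0L)
    return(data.table(tx = character(), gene = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      n_exons = integer()))
  data.table(
    tx = vapply(transcripts, `[[`, "", "id"),
    gene = if (is.null(gene_ids)) NA_character_ else gene_ids,
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    start = vapply(transcripts, function(t) t$exons$start[1L], 0),
    end = vapply(transcripts, function(t) t$exons$end[nrow(t$exons)], 0),
    strand = vapply(transcripts, `[[`, "", "strand"),
    n_exons = vapply(transcripts, function(t) nrow(t$exons), 0L)
  )
}

#' Genome annotation
#'
#' A collection of gene models plus chromosome sizes, with an overlap index
#' used by [query_overlapping()] and the downstream modules. Every gene must
#' lie within its chromosome's bounds.
#'
#' @param genes List of `gene_model` objects (or a list of `transcript_model`
#'   objects via `annotation_from_transcripts()`, one gene per transcript).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return An object of class `annotation`.
#' @export
annotation <- function(genes, chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  chrom_sizes <- structure(as.numeric(chrom_sizes), names = names(chrom_sizes))
  gene_ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  names(genes) <- gene_ids
  for (g in genes) {
    if (!g$chrom %in% names(chrom_sizes))
      stop("gene '", g$id, "' on unknown chromosome '", g$chrom, "'")
    if (g$end > chrom_sizes[[g$chrom]])
      stop("gene '", g$id, "' extends beyond chromosome '", g$chrom, "'")
  }
  txs <- unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
  if (is.null(txs)) txs <- list()
  tx_gene <- rep(gene_ids, vapply(genes, function(g) length(g$transcripts), 0L))
  tx_ids <- vapply(txs, `[[`, "", "id")
  if (anyDuplicated(tx_ids)) stop("duplicated transcript ids")
  names(txs) <- tx_ids
  gene_dt <- if (length(genes)) data.table(
    gene = gene_ids,
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    tss = vapply(genes, `[[`, 0, "tss")
  ) else data.table(gene = character(), chrom = character(), start = numeric(),
                    end = numeric(), strand = character(), tss = numeric())
  structure(list(genes = genes, chrom_sizes = chrom_sizes,
                 gene_table = gene_dt,
                 tx_table = tx_span_table(txs, tx_gene),
                 exon_table = tx_exon_table(txs, tx_gene),
                 transcripts = txs),
            class = "annotation")
}

#' @rdname annotation
#' @param transcripts List of `transcript_model` objects; each becomes a
#'   single-transcript gene named after the transcript.
#' @export
annotation_from_transcripts <- function(transcripts, chrom_sizes) {
  genes <- lapply(transcripts, function(t) gene_model(t$id, list(t)))
  annotation(genes, chrom_sizes)
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d gene(s), %d transcript(s), %d chromosome(s)\n",
              length(x$genes), length(x$transcripts), length(x$chrom_sizes)))
  invisible(x)
}

#' Query an annotation for models overlapping an interval
#'
#' Returns exactly the genes (or transcripts) whose span overlaps the query
#' interval by at least 1 bp, equivalently to a linear scan. Unknown
#' chromosomes yield an empty result.
#'
#' @param ann An [annotation()].
#' @param iv A [genomic_interval()].
#' @param level `"gene"` or `"transcript"`.
#' @return Sorted character vector of ids.
#' @export
query_overlapping <- function(ann, iv, level = c("gene", "transcript")) {
  level <- match.arg(level)
  dt <- if (level == "gene") ann$gene_table else ann$tx_table
  dt <- dt[chrom == iv$chrom]
  if (nrow(dt) == 0L) return(character())
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(iv$start + 1L, iv$end),
    IRanges::IRanges(dt$start + 1L, dt$end))
  ids <- dt[[if (level == "gene") "gene" else "tx"]][S4Vectors::subjectHits(hits)]
  sort(unique(ids))
}
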