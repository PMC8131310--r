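#' Read a two-column chrom.sizes file
#'
#' @param path Path to a `name TAB length` file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("chrom.sizes file must have two columns: ", path)
  sizes <- as.numeric(dt[[2L]])
  if (anyNA(sizes) || any(sizes <= 0)) stop("invalid chromosome length in ", path)
  structure(sizes, names = as.character(dt[[1L]]))
}

# Parse one GTF/GFF attribute string into a named character vector.
# Accepts both `key "value";` (GTF) and `key=value;` (GFF-like) dialects.
parse_attributes <- function(s) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_.]*)\\s+"([^"]*)"', s, perl = TRUE)[[1L]]
  out <- character()
  if (m[1L] != -1L) {
    for (tok in regmatches(s, gregexpr('([A-Za-z_][A-Za-z0-9_.]*)\\s+"([^"]*)"',
                                       s, perl = TRUE))[[1L]]) {
      key <- sub('\\s+".*', "", tok)
      val <- sub('^[^"]*"', "", sub('"$', "", tok))
      out[key] <- val
    }
    return(out)
  }
  for (tok in strsplit(s, ";", fixed = TRUE)[[1L]]) {
    tok <- trimws(tok)
    if (tok == "") next
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq > 0L)
      out[substr(tok, 1L, eq - 1L)] <- gsub('^"|"$', "",
                                            substr(tok, eq + 1L, nchar(tok)))
  }
  out
}

#' Read a GTF file into an annotation
#'
#' Parses 9-column GTF, keeping `exon` and `CDS` features. Exons are grouped
#' into transcripts by `transcript_id` and transcripts into genes by
#' `gene_id`. Coordinates are converted from GTF's 1-based inclusive to the
#' package's 0-based half-open convention here, and nowhere else. Both
#' `key "value";` and `key=value` attribute styles are accepted. Features
#' beyond chromosome bounds, malformed lines (with their line number), and
#' transcripts without exons are reported as errors rather than dropped.
#'
#' @param path Path to a GTF file.
#' @param chrom_sizes Named numeric vector (see [read_chrom_sizes()]).
#' @return An [annotation()].
#' @export
read_gtf <- function(path, chrom_sizes) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lnos <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lnos[which(nf != 9L)[1L]], " in ", path,
         ": expected 9 tab-separated columns, found ", nf[nf != 9L][1L])
  if (length(fields) == 0L) return(annotation(list(), chrom_sizes))
  dt <- data.table(
    chrom = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start1 = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    end1 = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L),
    line = lnos
  )
  dt <- dt[feature %in% c("exon", "CDS")]
  if (nrow(dt) == 0L) return(annotation(list(), chrom_sizes))
  bad <- dt[is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1]
  if (nrow(bad))
    stop("malformed GTF line ", bad$line[1L], " in ", path,
         ": invalid coordinates")
  if (any(!dt$strand %in% c("+", "-", ".")))
    stop("malformed GTF line ", dt$line[!dt$strand %in% c("+", "-", ".")][1L],
         " in ", path, ": strand must be +, - or .")
  unknown <- !dt$chrom %in% names(chrom_sizes)
  if (any(unknown))
    stop("GTF line ", dt$line[unknown][1L], " in ", path,
         ": unknown chromosome '", dt$chrom[unknown][1L], "'")
  oob <- dt$end1 > chrom_sizes[dt$chrom]
  if (any(oob))
    stop("GTF line ", dt$line[oob][1L], " in ", path,
         ": feature beyond chromosome bounds")
  al <- lapply(dt$attrs, parse_attributes)
  dt[, `:=`(tx = vapply(al, function(a) a[["transcript_id"]][1L], NA_character_),
            gene = vapply(al, function(a) a[["gene_id"]][1L], NA_character_),
            samples = vapply(al, function(a) {
              v <- a["source_samples"]; if (is.na(v)) "" else v
            }, ""))]
  if (anyNA(dt$tx) || anyNA(dt$gene))
    stop("GTF line ", dt$line[is.na(dt$tx) | is.na(dt$gene)][1L], " in ", path,
         ": missing transcript_id/gene_id attribute")
  # 1-based inclusive -> 0-based half-open
  dt[, `:=`(start = start1 - 1, end = end1)]
  setorder(dt, tx, start)
  txs <- list(); tx_gene <- character()
  for (tid in unique(dt$tx)) {
    sub <- dt[tx == tid]
    ex <- sub[feature == "exon"]
    if (nrow(ex) == 0L)
      stop("transcript '", tid, "' in ", path, " has no exon features")
    if (length(unique(sub$chrom)) != 1L)
      stop("transcript '", tid, "' in ", path, " spans multiple chromosomes")
    strands <- setdiff(unique(sub$strand), ".")
    if (length(strands) > 1L)
      stop("transcript '", tid, "' in ", path, " has conflicting strands")
    cds_rows <- sub[feature == "CDS"]
    cds <- if (nrow(cds_rows)) c(min(cds_rows$start), max(cds_rows$end)) else NULL
    samp <- unlist(strsplit(ex$samples[ex$samples != ""], ",", fixed = TRUE))
    txs[[tid]] <- transcript_model(
      tid, ex$chrom[1L], data.frame(start = ex$start, end = ex$end),
      strand = if (length(strands)) strands else "*",
      cds = cds, source_samples = unique(samp))
    tx_gene[tid] <- sub$gene[1L]
  }
  gene_ids <- unique(tx_gene[names(txs)])
  genes <- lapply(gene_ids, function(gid)
    gene_model(gid, unname(txs[names(tx_gene)[tx_gene == gid]])))
  annotation(genes, chrom_sizes)
}

#' Write transcript models as GTF
#'
#' Emits one `exon` line per exon (and a `CDS` line when a coding interval is
#' present), converting back to 1-based inclusive coordinates. Unknown strand
#' becomes `"."`. Output is sorted by chromosome, start and transcript id, so
#' identical inputs give byte-identical files. Attributes carry `gene_id`,
#' `transcript_id` and, when present, comma-separated `source_samples`.
#'
#' @param x An [annotation()] or a list of `transcript_model` objects.
#' @param path Output path.
#' @param gene_ids Optional character vector of gene ids parallel to a
#'   transcript list (defaults to the transcript ids).
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(x, path, gene_ids = NULL) {
  if (inherits(x, "annotation")) {
    txs <- unname(x$transcripts)
    gmap <- x$tx_table$gene
    names(gmap) <- x$tx_table$tx
    gene_ids <- gmap[vapply(txs, `[[`, "", "id")]
  } else {
    txs <- x
    if (is.null(gene_ids)) gene_ids <- vapply(txs, `[[`, "", "id")
  }
  ord <- order(vapply(txs, `[[`, "", "chrom"),
               vapply(txs, function(t) t$exons$start[1L], 0),
               vapply(txs, `[[`, "", "id"))
  out <- character()
  for (i in ord) {
    t <- txs[[i]]
    strand <- if (t$strand == "*") "." else t$strand
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene_ids[i], t$id)
    if (length(t$source_samples))
      attrs <- paste0(attrs, sprintf(' source_samples "%s";',
                                     paste(sort(t$source_samples),
                                           collapse = ",")))
    out <- c(out, sprintf("%s\tepireanno\texon\t%d\t%d\t.\t%s\t.\t%s",
                          t$chrom, as.integer(t$exons$start + 1),
                          as.integer(t$exons$end), strand, attrs))
    if (!is.null(t$cds))
      out <- c(out, sprintf("%s\tepireanno\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, as.integer(t$cds[1L] + 1),
                            as.integer(t$cds[2L]), strand, attrs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read ChIP-seq peaks (BED6 or ENCODE narrowPeak)
#'
#' BED6 peaks get a floor-midpoint center; narrowPeak peaks use the
#' 10th-column summit offset from the peak start, falling back to the
#' midpoint when the offset is `-1`. A summit offset outside the peak is an
#' error. Peaks are returned sorted by (chrom, start).
#'
#' @param path Path to the peak file (BED coordinates, already 0-based
#'   half-open).
#' @param dialect `"auto"` (by column count), `"bed6"` or `"narrowPeak"`.
#' @param tissue_label Label attached to the peak set (e.g. `"leaf"`).
#' @return A `peak_set`: data.table with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `center` and attribute `tissue_label`.
#' @export
read_peaks <- function(path, dialect = c("auto", "bed6", "narrowPeak"),
                       tissue_label = NA_character_) {
  dialect <- match.arg(dialect)
  dt <- fread(path, header = FALSE, sep = "\t")
  if (dialect == "auto")
    dialect <- if (ncol(dt) >= 10L) "narrowPeak" else "bed6"
  if (dialect == "bed6" && ncol(dt) < 4L)
    stop("BED6 peak file needs >= 4 columns: ", path)
  if (dialect == "narrowPeak" && ncol(dt) < 10L)
    stop("narrowPeak file needs 10 columns: ", path)
  peaks <- data.table(
    chrom = as.character(dt[[1L]]),
    start = as.numeric(dt[[2L]]),
    end = as.numeric(dt[[3L]]),
    name = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NA_character_,
    score = if (ncol(dt) >= 5L) as.numeric(dt[[5L]]) else 0
  )
  if (any(peaks$end <= peaks$start)) stop("empty peak interval in ", path)
  if (any(peaks$score < 0, na.rm = TRUE)) stop("negative peak score in ", path)
  if (dialect == "narrowPeak") {
    off <- as.numeric(dt[[10L]])
    mid <- floor((peaks$start + peaks$end) / 2)
    peaks[, center := ifelse(off == -1, mid, start + off)]
    bad <- peaks$center < peaks$start | peaks$center >= peaks$end
    if (any(bad))
      stop("summit offset outside peak at ", peaks$chrom[bad][1L], ":",
           peaks$start[bad][1L], " in ", path)
  } else {
    peaks[, center := floor((start + end) / 2)]
  }
  setorder(peaks, chrom, start)
  peaks[is.na(name) | name == "", name := sprintf("%s:%d-%d", chrom,
                                                 as.integer(start),
                                                 as.integer(end))]
  structure(peaks, class = c("peak_set", class(peaks)),
            tissue_label = tissue_label)
}

#' Read a bedGraph coverage track
#'
#' Runs may arrive unsorted; they are sorted and validated to be
#' non-overlapping (overlaps are an error naming the offending intervals).
#' Value lookup at an uncovered base is 0.
#'
#' @param path Path to a 4-column bedGraph.
#' @return A `coverage_track`: data.table with columns `chrom`, `start`,
#'   `end`, `value`, sorted, with attribute `normalization_state = "raw"`.
#' @export
read_bedgraph <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), value = as.numeric(value))]
  if (any(dt$end <= dt$start)) stop("empty bedGraph run in ", path)
  if (any(dt$value < 0)) stop("negative bedGraph value in ", path)
  setorder(dt, chrom, start)
  ov <- dt[, any(end[-.N] > start[-1L]), by = chrom][V1 == TRUE]
  if (nrow(ov)) {
    sub <- dt[chrom == ov$chrom[1L]]
    i <- which(sub$end[-nrow(sub)] > sub$start[-1L])[1L]
    stop("overlapping bedGraph runs in ", path, ": ", sub$chrom[i], ":",
         sub$start[i], "-", sub$end[i], " and ", sub$chrom[i + 1L], ":",
         sub$start[i + 1L], "-", sub$end[i + 1L])
  }
  structure(dt, class = c("coverage_track", class(dt)),
            normalization_state = "raw")
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  fwrite(as.data.table(track)[, .(chrom, start, end, value)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Coverage value at single base positions
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param pos Vector of 0-based base positions.
#' @return Numeric vector of values (0 where uncovered).
#' @export
coverage_value <- function(track, chrom, pos) {
  keep <- which(track$chrom == chrom)
  sub <- as.data.table(track)[keep]
  if (nrow(sub) == 0L) return(rep(0, length(pos)))
  idx <- findInterval(pos, sub$start)
  val <- rep(0, length(pos))
  hit <- idx > 0L
  hit[hit] <- pos[hit] < sub$end[idx[hit]]
  val[hit] <- sub$value[idx[hit]]
  val
}

# Integral of the step function from -Inf to x (vectorized over x), for one
# chromosome's sorted, non-overlapping runs. Used for exact bin means.
coverage_integral <- function(sub, x) {
  if (nrow(sub) == 0L) return(rep(0, length(x)))
  w <- sub$end - sub$start
  cum <- cumsum(sub$value * w)
  idx <- findInterval(x, sub$start)
  out <- rep(0, length(x))
  pos <- idx > 0L
  before <- c(0, cum)[idx[pos]]
  inrun <- pmin(pmax(x[pos] - sub$start[idx[pos]], 0), w[idx[pos]])
  out[pos] <- before + sub$value[idx[pos]] * inrun
  out
}

#' Mean coverage over an interval
#'
#' Exact mean of the stepwise track over `[start, end)`, counting uncovered
#' bases as 0.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return Numeric scalar.
#' @export
coverage_mean <- function(track, chrom, start, end) {
  if (end <= start) stop("end must exceed start")
  keep <- which(track$chrom == chrom)
  sub <- as.data.table(track)[keep]
  (coverage_integral(sub, end) - coverage_integral(sub, start)) / (end - start)
}

#' Read a transcript-by-sample FPKM matrix
#'
#' Expects a header row of sample ids with transcript ids in the first
#' column. Missing cells become 0; duplicated transcript ids and negative
#' FPKM values are errors.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rownames = transcript ids, colnames = sample ids.
#' @export
read_expression <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated transcript id '", ids[duplicated(ids)][1L], "' in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("negative FPKM in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  dt <- data.table(transcript_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
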