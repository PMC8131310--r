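#' Configuration for the synthetic fixture generator
#'
#' Defines the study conditions emulated by [generate_fixture()]: a toy
#' multi-chromosome genome, a known annotation, planted novel transcripts,
#' per-sample assemblies with dropout and optional boundary jitter,
#' TSS-anchored H3K4me3 peaks per tissue, 5'-weighted coverage tracks and a
#' transcript-by-sample FPKM matrix. Defaults are the package's reference
#' conditions: 300 planted novels observed by 10 unstranded assemblies with
#' 30% per-sample dropout, peaks of width 400 bp centered 500 bp upstream of
#' each TSS, no decoy peaks and no boundary jitter.
#'
#' @param seed RNG seed; every random choice derives from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_known_genes Genes in the known annotation.
#' @param n_novel Planted novel transcripts (zero exonic overlap with the
#'   known annotation, by construction).
#' @param exon_count_range,exon_length_range,intron_length_range Known-gene
#'   structure ranges (bp).
#' @param novel_exon_count_range,novel_exon_length_range Novel-transcript
#'   structure ranges; novels are mostly single-exon and shorter than known
#'   genes.
#' @param n_samples RNA-seq assemblies to simulate.
#' @param tissues Tissue labels; samples are assigned round-robin and one
#'   peak set plus one coverage track is emitted per tissue.
#' @param dropout Probability that a planted novel is absent from a given
#'   sample's assembly.
#' @param jitter_sd SD (bp) of Gaussian exon-boundary jitter in assemblies.
#' @param peak_offset Peak center placed this many bp upstream of the TSS
#'   (strand-aware).
#' @param peak_width Peak width in bp.
#' @param decoy_frac Decoy peaks (random intergenic placement) as a fraction
#'   of real peaks.
#' @param expr_meanlog,expr_sdlog Lognormal parameters of baseline FPKM.
#' @param tissue_sdlog Lognormal SD of the per-tissue expression factor.
#' @param gap_range Range (bp) of intergenic gaps between placed features.
#' @param min_match_fraction Exonic-overlap fraction (of the shorter
#'   transcript) for [evaluate_recovery()] matching.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_chroms = 4, chrom_length = 1200000,
                         n_known_genes = 150, n_novel = 300,
                         exon_count_range = c(1, 5),
                         exon_length_range = c(200, 1500),
                         intron_length_range = c(100, 2000),
                         novel_exon_count_range = c(1, 2),
                         novel_exon_length_range = c(200, 1500),
                         n_samples = 10,
                         tissues = c("leaf", "stem", "root"),
                         dropout = 0.3, jitter_sd = 0,
                         peak_offset = 500, peak_width = 400,
                         decoy_frac = 0,
                         expr_meanlog = log(10), expr_sdlog = 1,
                         tissue_sdlog = 0.25,
                         gap_range = c(3000, 8000),
                         min_match_fraction = 0.5) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$chrom_length, cfg$n_known_genes, cfg$n_novel,
              cfg$n_samples, cfg$peak_width)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$dropout < 0 || cfg$dropout > 1) stop("dropout must be in [0,1]")
  if (cfg$decoy_frac < 0 || cfg$decoy_frac > 1)
    stop("decoy_frac must be in [0,1]")
  if (cfg$jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (length(cfg$tissues) < 1L) stop("need >= 1 tissue")
  structure(cfg, class = "synth_config")
}

# Draw one feature structure (exon chain lengths); returns exon data.frame
# relative to 0 plus total span length.
.draw_structure <- function(n_ex_range, ex_range, in_range) {
  n_ex <- sample(n_ex_range[1L]:n_ex_range[2L], 1L)
  ex_len <- sample(ex_range[1L]:ex_range[2L], n_ex, replace = TRUE)
  in_len <- if (n_ex > 1L)
    sample(in_range[1L]:in_range[2L], n_ex - 1L, replace = TRUE) else integer()
  starts <- cumsum(c(0, ex_len[-n_ex] + in_len))
  data.frame(start = starts, end = starts + ex_len)
}

#' Generate a synthetic fixture emulating the pipeline's inputs
#'
#' Places known genes and planted novel transcripts in non-overlapping
#' genomic space (erroring before any file is written when they cannot fit),
#' then derives every downstream input from them:
#' \itemize{
#'   \item per-sample assembly GTFs: an unstranded copy of every known
#'     transcript plus each planted novel that survives per-sample dropout,
#'     with optional exon-boundary jitter;
#'   \item per-tissue peak BED6 files: one peak per expressed model with
#'     center `peak_offset` bp upstream of the TSS (strand-aware) — known
#'     genes in every tissue, novels only in their true support tissues —
#'     plus optional intergenic decoy peaks;
#'   \item per-tissue bedGraph coverage: a 5'-weighted kernel (linearly
#'     decaying along the body from the TSS) per expressed model, scaled by
#'     its tissue FPKM;
#'   \item a transcript-by-sample FPKM matrix (samples of one tissue share
#'     the tissue's expression values);
#'   \item `truth.json` and an in-memory truth set.
#' }
#' Identical configurations produce byte-identical files.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `truth` (planted novels
#'   with true strand/tissues, peak catalog, expression), plus in-memory
#'   `known` ([annotation()]), `assemblies`, `peaksets`, `tracks`, `expr`.
#' @export
generate_fixture <- function(config, dir = tempfile("fixture")) {
  stopifnot(inherits(config, "synth_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                 chroms)
  margin <- 5000

  ## 1. plan placement (no files written until everything fits)
  kind <- sample(c(rep("known", config$n_known_genes),
                   rep("novel", config$n_novel)))
  feats <- vector("list", length(kind))
  ci <- 1L
  pos <- margin
  for (i in seq_along(kind)) {
    ex <- if (kind[i] == "known")
      .draw_structure(config$exon_count_range, config$exon_length_range,
                      config$intron_length_range)
    else
      .draw_structure(config$novel_exon_count_range,
                      config$novel_exon_length_range,
                      config$intron_length_range)
    strand <- sample(c("+", "-"), 1L)
    gap <- sample(config$gap_range[1L]:config$gap_range[2L], 1L)
    len <- ex$end[nrow(ex)]
    if (pos + len > config$chrom_length - margin) {
      ci <- ci + 1L
      pos <- margin
      if (ci > config$n_chroms)
        stop("config infeasible: features do not fit in ", config$n_chroms,
             " chromosome(s) of ", config$chrom_length, " bp")
      if (pos + len > config$chrom_length - margin)
        stop("config infeasible: feature longer than a chromosome")
    }
    feats[[i]] <- list(kind = kind[i], chrom = chroms[ci],
                       exons = data.frame(start = ex$start + pos,
                                          end = ex$end + pos),
                       strand = strand)
    pos <- pos + len + gap
  }

  ## 2. known annotation and planted novels, ids in genomic order
  ord <- order(vapply(feats, `[[`, "", "chrom"),
               vapply(feats, function(f) f$exons$start[1L], 0))
  feats <- feats[ord]
  known_tx <- list(); novel_tx <- list()
  for (f in feats) {
    if (f$kind == "known") {
      i <- length(known_tx) + 1L
      ex <- f$exons
      span <- c(ex$start[1L], ex$end[nrow(ex)])
      u5 <- min(150, floor((ex$end[1L] - ex$start[1L]) / 3))
      u3 <- min(250, floor((ex$end[nrow(ex)] - ex$start[nrow(ex)]) / 3))
      cds <- if (f$strand == "-") c(span[1L] + u3, span[2L] - u5) else
        c(span[1L] + u5, span[2L] - u3)
      known_tx[[i]] <- transcript_model(sprintf("KG%05d.t1", i), f$chrom, ex,
                                        strand = f$strand, cds = cds)
    } else {
      i <- length(novel_tx) + 1L
      novel_tx[[i]] <- transcript_model(sprintf("NVL%05d", i), f$chrom,
                                        f$exons, strand = f$strand)
    }
  }
  genes <- lapply(seq_along(known_tx), function(i)
    gene_model(sprintf("KG%05d", i), known_tx[i]))
  known <- annotation(genes, chrom_sizes)

  ## 3. true tissue-support pattern per novel
  nt <- length(config$tissues)
  truth_tissues <- lapply(seq_along(novel_tx), function(i) {
    u <- stats::runif(1)
    if (u < 0.5 || nt == 1L) config$tissues
    else if (u < 0.8) sample(config$tissues, 1L)
    else sort(sample(config$tissues, min(2L, nt)))
  })

  ## 4. expression: baseline x per-tissue factor; samples share tissue values
  samples <- sprintf("%s_s%02d",
                     config$tissues[((seq_len(config$n_samples) - 1L) %% nt) + 1L],
                     seq_len(config$n_samples))
  sample_tissue <- config$tissues[((seq_len(config$n_samples) - 1L) %% nt) + 1L]
  all_ids <- c(vapply(genes, `[[`, "", "id"),
               vapply(novel_tx, `[[`, "", "id"))
  n_feat <- length(all_ids)
  base_expr <- stats::rlnorm(n_feat, config$expr_meanlog, config$expr_sdlog)
  tissue_factor <- matrix(stats::rlnorm(n_feat * nt, 0, config$tissue_sdlog),
                          n_feat, nt, dimnames = list(all_ids, config$tissues))
  tissue_fpkm <- base_expr * tissue_factor
  for (i in seq_along(novel_tx)) {
    off_t <- setdiff(config$tissues, truth_tissues[[i]])
    tissue_fpkm[novel_tx[[i]]$id, off_t] <- 0
  }
  expr <- round(tissue_fpkm[, sample_tissue, drop = FALSE], 4)
  colnames(expr) <- samples

  ## 5. assemblies: known copies + novels surviving dropout, optional jitter
  presence <- matrix(stats::runif(length(novel_tx) * config$n_samples) >=
                       config$dropout,
                     length(novel_tx), config$n_samples)
  jitter_exons <- function(ex) {
    if (config$jitter_sd == 0) return(ex)
    sh <- round(stats::rnorm(2L * nrow(ex), 0, config$jitter_sd))
    sh <- pmax(pmin(sh, 80), -80)
    s <- ex$start + sh[seq_len(nrow(ex))]
    e <- ex$end + sh[nrow(ex) + seq_len(nrow(ex))]
    e <- pmax(e, s + 50)
    if (nrow(ex) > 1L) for (j in 2:nrow(ex)) s[j] <- max(s[j], e[j - 1L] + 20)
    e <- pmax(e, s + 50)
    data.frame(start = pmax(s, 0), end = e)
  }
  assemblies <- list()
  for (si in seq_len(config$n_samples)) {
    txs <- list()
    for (t in known_tx)
      txs[[length(txs) + 1L]] <- transcript_model(
        sprintf("%s.%s", samples[si], t$id), t$chrom, jitter_exons(t$exons),
        strand = "*", source_samples = samples[si])
    for (vi in seq_along(novel_tx)) if (presence[vi, si]) {
      t <- novel_tx[[vi]]
      txs[[length(txs) + 1L]] <- transcript_model(
        sprintf("%s.%s", samples[si], t$id), t$chrom, jitter_exons(t$exons),
        strand = "*", source_samples = samples[si])
    }
    assemblies[[samples[si]]] <- txs
  }

  ## 6. peaks: one per expressed model per tissue, anchored at TSS - offset
  half <- floor(config$peak_width / 2)
  model_peak <- function(t) {
    span <- c(t$exons$start[1L], t$exons$end[nrow(t$exons)])
    center <- if (t$strand == "-") span[2L] + config$peak_offset else
      span[1L] - config$peak_offset
    c(center - half, center - half + config$peak_width)
  }
  span_dt <- rbind(
    known$gene_table[, .(chrom, start, end)],
    tx_span_table(novel_tx)[, .(chrom, start, end)])
  peaksets <- list()
  for (tis in config$tissues) {
    rows <- list()
    for (i in seq_along(known_tx)) {
      p <- model_peak(known_tx[[i]])
      rows[[length(rows) + 1L]] <- data.table(
        chrom = known_tx[[i]]$chrom, start = p[1L], end = p[2L],
        name = sprintf("%s_pk_%s", tis, genes[[i]]$id),
        score = round(stats::runif(1, 100, 1000)))
    }
    for (i in seq_along(novel_tx)) if (tis %in% truth_tissues[[i]]) {
      p <- model_peak(novel_tx[[i]])
      rows[[length(rows) + 1L]] <- data.table(
        chrom = novel_tx[[i]]$chrom, start = p[1L], end = p[2L],
        name = sprintf("%s_pk_%s", tis, novel_tx[[i]]$id),
        score = round(stats::runif(1, 100, 1000)))
    }
    n_decoy <- round(config$decoy_frac * length(rows))
    made <- 0L; tries <- 0L
    while (made < n_decoy && tries < 50L * n_decoy) {
      tries <- tries + 1L
      cm <- sample(chroms, 1L)
      c0 <- sample(seq(margin, config$chrom_length - margin), 1L)
      near <- span_dt[chrom == cm &
                        start - 2500 - config$peak_offset < c0 + half &
                        end + 2500 + config$peak_offset > c0 - half]
      if (nrow(near)) next
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.table(
        chrom = cm, start = c0 - half, end = c0 - half + config$peak_width,
        name = sprintf("%s_decoy_%03d", tis, made),
        score = round(stats::runif(1, 100, 1000)))
    }
    pk <- rbindlist(rows)
    pk[, start := pmax(start, 0)]
    pk[, center := floor((start + end) / 2)]
    setorder(pk, chrom, start, name)
    peaksets[[tis]] <- structure(pk, class = c("peak_set", class(pk)),
                                 tissue_label = tis)
  }

  ## 7. coverage: 5'-weighted kernel per expressed model, 25-bp steps
  bin_w <- 25
  tracks <- list()
  all_models <- c(known_tx, novel_tx)
  for (tis in config$tissues) {
    pieces <- list()
    for (t in all_models) {
      fp <- tissue_fpkm[sub("\\.t1$", "", t$id), tis]
      if (fp <= 0) next
      span <- c(t$exons$start[1L], t$exons$end[nrow(t$exons)])
      L <- span[2L] - span[1L]
      starts <- seq(span[1L], span[2L] - 1, by = bin_w)
      ends <- pmin(starts + bin_w, span[2L])
      mid <- (starts + ends) / 2
      d5 <- if (t$strand == "-") span[2L] - mid else mid - span[1L]
      pieces[[length(pieces) + 1L]] <- data.table(
        chrom = t$chrom, start = starts, end = ends,
        value = fp * (1 - 0.9 * d5 / L))
    }
    trk <- rbindlist(pieces)
    trk <- trk[, .(value = round(sum(value), 4)), by = .(chrom, start, end)]
    setorder(trk, chrom, start)
    tracks[[tis]] <- structure(trk, class = c("coverage_track", class(trk)),
                               normalization_state = "raw")
  }

  ## 8. write everything
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "assemblies"), showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  paths <- list(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    known_gtf = file.path(dir, "known.gtf"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"),
    assemblies = stats::setNames(
      file.path(dir, "assemblies", paste0(samples, ".gtf")), samples),
    peaks = stats::setNames(
      file.path(dir, "peaks", paste0(config$tissues, ".bed")),
      config$tissues),
    coverage = stats::setNames(
      file.path(dir, "coverage", paste0(config$tissues, ".bedGraph")),
      config$tissues))
  writeLines(sprintf("%s\t%d", chroms, as.integer(chrom_sizes)),
             paths$chrom_sizes)
  write_gtf(known, paths$known_gtf)
  for (s in samples) write_gtf(assemblies[[s]], paths$assemblies[[s]])
  for (tis in config$tissues) {
    pk <- as.data.table(peaksets[[tis]])
    fwrite(pk[, .(chrom, as.integer(start), as.integer(end), name,
                  as.integer(score), ".")],
           paths$peaks[[tis]], sep = "\t", col.names = FALSE)
    write_bedgraph(tracks[[tis]], paths$coverage[[tis]])
  }
  write_expression(expr, paths$expression)

  truth <- list(
    novel = novel_tx,
    tissues = stats::setNames(truth_tissues,
                              vapply(novel_tx, `[[`, "", "id")),
    expression = expr,
    n_tissues = nt,
    config = config)
  jsonlite::write_json(
    lapply(stats::setNames(seq_along(novel_tx),
                           vapply(novel_tx, `[[`, "", "id")),
           function(i) {
             t <- novel_tx[[i]]
             list(chrom = t$chrom, start = t$exons$start[1L],
                  end = t$exons$end[nrow(t$exons)], strand = t$strand,
                  n_exons = nrow(t$exons), tissues = truth_tissues[[i]])
           }),
    paths$truth, auto_unbox = TRUE, digits = NA)

  list(paths = paths, truth = truth, known = known, assemblies = assemblies,
       peaksets = peaksets, tracks = tracks, expr = expr,
       chrom_sizes = chrom_sizes)
}

#' Evaluate discovery output against the planted truth
#'
#' A predicted novel transcript matches a truth transcript when their exonic
#' overlap is at least `min_match_fraction` of the shorter transcript's
#' exonic bp. Reports precision (matched predictions over predictions;
#' 1.0 by convention, flagged, when there are none), recall (matched truths
#' over truths), strand accuracy among matched pairs whose truth strand is
#' known, and a tissue-specificity confusion table (truth label from the
#' planted tissue pattern vs the predicted `specificity` label when a
#' support table is supplied).
#'
#' @param predicted List of predicted `transcript_model`s (consensus strand
#'   applied), e.g. `discover_novel(...)$novel`.
#' @param truth Truth set from [generate_fixture()].
#' @param support Optional `support_table` for the specificity confusion.
#' @param min_match_fraction Overlap fraction threshold (default from the
#'   truth's config, else 0.5).
#' @return List of metrics; see Details.
#' @export
evaluate_recovery <- function(predicted, truth, support = NULL,
                              min_match_fraction = NULL) {
  if (is.null(min_match_fraction))
    min_match_fraction <- truth$config$min_match_fraction %||% 0.5
  tr <- truth$novel
  n_pred <- length(predicted); n_truth <- length(tr)
  match_of <- rep(NA_integer_, n_pred)
  truth_hit <- rep(FALSE, n_truth)
  for (i in seq_len(n_pred)) {
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(n_truth)) {
      if (predicted[[i]]$chrom != tr[[j]]$chrom) next
      ov <- exonic_overlap_bp(predicted[[i]], tr[[j]])
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (!is.na(best_j)) {
      shorter <- min(exonic_bp(predicted[[i]]), exonic_bp(tr[[best_j]]))
      if (best >= min_match_fraction * shorter) {
        match_of[i] <- best_j
        truth_hit[best_j] <- TRUE
      }
    }
  }
  matched <- !is.na(match_of)
  precision <- if (n_pred == 0L) 1.0 else sum(matched) / n_pred
  recall <- if (n_truth == 0L) 1.0 else sum(truth_hit) / n_truth
  truth_strand <- vapply(tr, `[[`, "", "strand")
  known_strand <- matched & truth_strand[match_of] %in% c("+", "-")
  strand_accuracy <- if (any(known_strand)) {
    pred_strand <- vapply(predicted, `[[`, "", "strand")
    mean(pred_strand[known_strand] ==
           truth_strand[match_of[known_strand]])
  } else NA_real_
  confusion <- NULL
  if (!is.null(support) && any(matched)) {
    truth_label <- vapply(truth$tissues, function(ts) {
      k <- length(ts)
      if (k == truth$n_tissues) "all-tissues"
      else if (k == 1L) "single-tissue" else "subset"
    }, "")
    pred_ids <- vapply(predicted, `[[`, "", "id")
    spec_lab <- stats::setNames(support$specificity, support$id)[pred_ids]
    tl <- truth_label[vapply(tr, `[[`, "", "id")[match_of[matched]]]
    confusion <- table(truth = tl, predicted = spec_lab[matched])
  }
  list(precision = precision, recall = recall,
       strand_accuracy = strand_accuracy,
       n_predicted = n_pred, n_truth = n_truth, n_matched = sum(matched),
       degenerate = n_pred == 0L,
       specificity_confusion = confusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
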