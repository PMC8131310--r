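#' Pipeline configuration
#'
#' Collects the input paths and tunable parameters of the discovery and
#' reannotation pipeline. All defaults mirror the protocol the package
#' implements: a 2 kb promoter/upstream window, a 2 kb peak-center distance
#' for strand inference, a 0.6 log2 fold-change threshold with pseudocount
#' 1, 1 kb meta-gene flanks in 50 bp bins with a 100-bin body, nine
#' expression quantiles and six TSS-signal clusters. Every referenced path
#' must exist at validation time.
#'
#' @param known_gtf Reference annotation GTF.
#' @param chrom_sizes Two-column chrom.sizes file.
#' @param assemblies Named character vector of per-sample assembly GTFs
#'   (names = sample ids; defaults to file base names).
#' @param peaks Named character vector of per-tissue peak files (BED6 or
#'   narrowPeak; names = tissue labels).
#' @param bedgraphs Optional named character vector of per-tissue bedGraph
#'   coverage tracks.
#' @param expression Optional expression TSV.
#' @param out_dir Output directory for [run_discover()]/[run_annotate()].
#' @param promoter_bp,strand_max_center_dist,log2fc_threshold,pseudocount,flank_bp,body_bins,flank_bin_bp,n_quantiles,k_clusters,min_match_fraction,seed
#'   Tunable parameters; see the corresponding stage functions.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(known_gtf, chrom_sizes, assemblies, peaks,
                            bedgraphs = NULL, expression = NULL,
                            out_dir = tempfile("epireanno"),
                            promoter_bp = 2000,
                            strand_max_center_dist = 2000,
                            log2fc_threshold = 0.6, pseudocount = 1,
                            flank_bp = 1000, body_bins = 100,
                            flank_bin_bp = 50, n_quantiles = 9,
                            k_clusters = 6, min_match_fraction = 0.5,
                            seed = 1) {
  if (is.null(names(assemblies)))
    names(assemblies) <- sub("\\.gtf$", "", basename(assemblies))
  if (is.null(names(peaks)))
    stop("peaks must be a named vector (names are tissue labels)")
  for (p in c(known_gtf, chrom_sizes, unname(assemblies), unname(peaks),
              unname(bedgraphs), expression))
    if (!file.exists(p)) stop("no such file: ", p)
  bp_params <- c(promoter_bp, strand_max_center_dist, flank_bp, flank_bin_bp)
  if (any(bp_params <= 0)) stop("bp parameters must be positive")
  cfg <- as.list(environment())
  cfg$bp_params <- NULL
  cfg$p <- NULL
  structure(cfg, class = "pipeline_config")
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  invisible(msg)
}

#' Run the discovery stage of the pipeline
#'
#' Executes merge, subtraction, peak co-occurrence, strand inference and
#' tissue-specificity labeling on the configured inputs, writing
#' `novel.gtf`, `support_table.tsv` and a run log (`discover.log`) that
#' records input checksums, parameters and per-stage counts, so the run
#' summary is reproducible from the log alone. Outputs are byte-identical
#' across reruns on identical inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the [discover_novel()] result list, augmented with
#'   `paths`.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- read_chrom_sizes(config$chrom_sizes)
  known <- read_gtf(config$known_gtf, sizes)
  assemblies <- lapply(names(config$assemblies), function(s) {
    ann <- read_gtf(config$assemblies[[s]], sizes)
    lapply(unname(ann$transcripts), function(t) {
      t$source_samples <- union(t$source_samples, s)
      t
    })
  })
  names(assemblies) <- names(config$assemblies)
  peaksets <- lapply(names(config$peaks), function(tis)
    read_peaks(config$peaks[[tis]], tissue_label = tis))
  names(peaksets) <- names(config$peaks)

  res <- discover_novel(assemblies, known, peaksets,
                        max_center_dist = config$strand_max_center_dist)

  paths <- list(novel_gtf = file.path(config$out_dir, "novel.gtf"),
                support = file.path(config$out_dir, "support_table.tsv"),
                log = file.path(config$out_dir, "discover.log"))
  write_gtf(res$novel, paths$novel_gtf)
  fwrite(as.data.table(res$support), paths$support, sep = "\t")

  con <- file(paths$log, "w")
  on.exit(close(con))
  .log_line(con, "epireanno discover")
  for (p in c(config$known_gtf, config$chrom_sizes, unname(config$assemblies),
              unname(config$peaks)))
    .log_line(con, "input\t", p, "\tmd5=", unname(tools::md5sum(p)))
  .log_line(con, "param\tstrand_max_center_dist\t",
            config$strand_max_center_dist)
  for (nm in names(res$counts))
    .log_line(con, "count\t", nm, "\t", res$counts[[nm]])
  res$paths <- paths
  invisible(res)
}

#' Run the reannotation/report stage of the pipeline
#'
#' Builds the six-class region partition for the chosen annotation variant
#' (`known`, or `known+novel` with the discovery output appended as
#' single-transcript genes), and writes `region_fractions.tsv`, one
#' `peak_distribution.<tissue>.tsv` per tissue and `associated_genes.tsv`.
#' Before/after comparisons are a diff of two reports; adding novel models
#' can only convert intergenic bases to genic ones, so the intergenic
#' fractions never increase from `known` to `known+novel`.
#'
#' @param config A [pipeline_config()].
#' @param annotation_variant `"known"` or `"known+novel"` (requires
#'   `run_discover()` outputs in `config$out_dir`).
#' @return Invisibly, a list with the partition, `region_fractions`,
#'   per-tissue `peak_distribution`, `association` and output `paths`.
#' @export
run_annotate <- function(config, annotation_variant = c("known",
                                                        "known+novel")) {
  annotation_variant <- match.arg(annotation_variant)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- read_chrom_sizes(config$chrom_sizes)
  ann <- read_gtf(config$known_gtf, sizes)
  if (annotation_variant == "known+novel") {
    novel_path <- file.path(config$out_dir, "novel.gtf")
    if (!file.exists(novel_path))
      stop("annotate with 'known+novel' requires ", novel_path,
           " (run_discover first)")
    novel <- read_gtf(novel_path, sizes)
    ann <- annotation(c(ann$genes, novel$genes), sizes)
  }
  part <- build_region_partition(ann, promoter_bp = config$promoter_bp)
  rf <- region_fractions(part)
  peaksets <- lapply(names(config$peaks), function(tis)
    read_peaks(config$peaks[[tis]], tissue_label = tis))
  names(peaksets) <- names(config$peaks)
  pd <- lapply(peaksets, peak_region_distribution, partition = part)
  assoc <- lapply(peaksets, associate_peaks_to_genes, ann = ann,
                  upstream_bp = config$promoter_bp)

  tag <- if (annotation_variant == "known") "known" else "reannotated"
  paths <- list(
    region_fractions = file.path(config$out_dir,
                                 sprintf("region_fractions.%s.tsv", tag)),
    association = file.path(config$out_dir,
                            sprintf("associated_genes.%s.tsv", tag)))
  fwrite(data.table(label = names(rf), percent = round(unname(rf), 6)),
         paths$region_fractions, sep = "\t")
  for (tis in names(pd)) {
    p <- file.path(config$out_dir,
                   sprintf("peak_distribution.%s.%s.tsv", tis, tag))
    fwrite(data.table(label = names(pd[[tis]]),
                      percent = round(unname(pd[[tis]]), 6)), p, sep = "\t")
    paths[[paste0("peak_distribution_", tis)]] <- p
  }
  assoc_dt <- rbindlist(lapply(names(assoc), function(tis)
    data.table(tissue = tis, gene = assoc[[tis]]$genes)))
  fwrite(assoc_dt, paths$association, sep = "\t")
  invisible(list(partition = part, region_fractions = rf,
                 peak_distribution = pd, association = assoc, paths = paths))
}
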