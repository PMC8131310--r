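# Union-find with path halving; the core of single-linkage merging.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1L]); rb <- find(edges[k, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, 0L)
}

strands_compatible <- function(a, b) !((a == "+" & b == "-") | (a == "-" & b == "+"))

# Transcript-pair edges: same chrom, exonic overlap >= 1 bp, compatible strands.
overlap_edges <- function(spans, exons) {
  edges <- matrix(0L, 0L, 2L)
  for (cm in unique(exons$chrom)) {
    ex <- exons[chrom == cm]
    ir <- IRanges::IRanges(ex$start + 1L, ex$end)
    h <- IRanges::findOverlaps(ir, ir)
    qi <- ex$idx[S4Vectors::queryHits(h)]
    si <- ex$idx[S4Vectors::subjectHits(h)]
    keep <- qi < si
    if (!any(keep)) next
    pair <- unique(data.table(a = qi[keep], b = si[keep]))
    ok <- strands_compatible(spans$strand[pair$a], spans$strand[pair$b])
    if (any(ok)) edges <- rbind(edges, cbind(pair$a[ok], pair$b[ok]))
  }
  edges
}

#' Merge per-sample transcript assemblies
#'
#' Clusters transcripts across assemblies by single linkage over the relation
#' "same chromosome AND >= 1 bp exonic overlap AND compatible strands"
#' (unknown strand is compatible with anything; forward is incompatible with
#' reverse). Each cluster becomes one merged transcript whose exons are the
#' interval union of the members' exons (overlapping or book-ended exons
#' coalesced) and whose strand is the single known strand among members, or
#' unknown. Components that would mix forward and reverse members through
#' unknown-strand bridges are split: reverse-strand members are re-clustered
#' on their own, the remainder (forward plus unknown) likewise.
#'
#' The operation is idempotent and invariant to the order of the input
#' assemblies; output is sorted by (chrom, start) and assigned ids
#' `MRG_00001, ...`.
#'
#' @param assemblies A list of transcript sets (each a list of
#'   `transcript_model`), one per sample, or a single flat list of models.
#' @return List of merged `transcript_model`s, each carrying a `members`
#'   character vector of the contributing transcript ids.
#' @export
merge_assemblies <- function(assemblies) {
  if (length(assemblies) && inherits(assemblies[[1L]], "transcript_model"))
    assemblies <- list(assemblies)
  txs <- unlist(assemblies, recursive = FALSE)
  if (length(txs) == 0L) return(list())
  spans <- tx_span_table(txs)
  spans[, idx := .I]
  exons <- tx_exon_table(txs)
  exons[, idx := rep(seq_along(txs),
                     vapply(txs, function(t) nrow(t$exons), 0L))]
  edges <- overlap_edges(spans, exons)
  comp <- uf_components(length(txs), edges)

  clusters <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    st <- spans$strand[members]
    if (any(st == "+") && any(st == "-")) {
      # split by strand, then re-cluster each side independently
      minus <- members[st == "-"]
      rest <- members[st != "-"]
      for (side in list(rest, minus)) {
        sub_edges <- edges[edges[, 1L] %in% side & edges[, 2L] %in% side, ,
                           drop = FALSE]
        remap <- match(sub_edges, side)
        dim(remap) <- dim(sub_edges)
        subcomp <- uf_components(length(side), remap)
        for (sc in unique(subcomp))
          clusters[[length(clusters) + 1L]] <- side[subcomp == sc]
      }
    } else {
      clusters[[length(clusters) + 1L]] <- members
    }
  }

  merged <- lapply(clusters, function(members) {
    mem_tx <- txs[members]
    ex <- tx_exon_table(mem_tx)
    red <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    st <- setdiff(unique(vapply(mem_tx, `[[`, "", "strand")), "*")
    t <- transcript_model(
      "tmp", mem_tx[[1L]]$chrom,
      data.frame(start = IRanges::start(red) - 1, end = IRanges::end(red)),
      strand = if (length(st) == 1L) st else "*",
      source_samples = unique(unlist(lapply(mem_tx, `[[`, "source_samples"))))
    t$members <- sort(vapply(mem_tx, `[[`, "", "id"))
    t
  })
  ord <- order(vapply(merged, `[[`, "", "chrom"),
               vapply(merged, function(t) t$exons$start[1L], 0),
               vapply(merged, function(t) t$exons$end[nrow(t$exons)], 0),
               vapply(merged, function(t) paste(t$members, collapse = ",") , ""))
  merged <- merged[ord]
  for (i in seq_along(merged)) merged[[i]]$id <- sprintf("MRG_%05d", i)
  merged
}

# Intron table of an annotation: per transcript, gaps between consecutive exons.
annotation_introns <- function(known) {
  ex <- known$exon_table
  if (nrow(ex) == 0L)
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  ex <- ex[order(tx, start)]
  ex[, {
    if (.N > 1L) list(chrom = chrom[-1L], start = end[-.N], istart = start[-1L])
    else list(chrom = character(), start = numeric(), istart = numeric())
  }, by = tx][, .(chrom, start, end = istart)]
}

#' Subtract a known annotation from merged transcripts
#'
#' A merged transcript is a candidate novel transcript iff its exons overlap
#' no known transcript's exons by even 1 bp (any strand). Candidates lying
#' entirely within an intron of a known transcript are kept and flagged
#' `"intronic"`; all other candidates are flagged `"intergenic"`.
#'
#' @param merged List of `transcript_model`s from [merge_assemblies()].
#' @param known An [annotation()].
#' @return List with `candidates` (transcript list, each with a `placement`
#'   field), `n_input` and `n_removed`.
#' @export
subtract_known <- function(merged, known) {
  if (length(merged) == 0L)
    return(list(candidates = list(), n_input = 0L, n_removed = 0L))
  mex <- tx_exon_table(merged)
  mex[, idx := rep(seq_along(merged),
                   vapply(merged, function(t) nrow(t$exons), 0L))]
  kex <- known$exon_table
  hit <- rep(FALSE, length(merged))
  for (cm in intersect(unique(mex$chrom), unique(kex$chrom))) {
    m <- mex[chrom == cm]; k <- kex[chrom == cm]
    h <- IRanges::findOverlaps(IRanges::IRanges(m$start + 1L, m$end),
                               IRanges::IRanges(k$start + 1L, k$end))
    hit[unique(m$idx[S4Vectors::queryHits(h)])] <- TRUE
  }
  candidates <- merged[!hit]
  introns <- annotation_introns(known)
  for (i in seq_along(candidates)) {
    t <- candidates[[i]]
    s <- t$exons$start[1L]; e <- t$exons$end[nrow(t$exons)]
    inside <- introns[chrom == t$chrom & start <= s & e <= end]
    candidates[[i]]$placement <- if (nrow(inside)) "intronic" else "intergenic"
  }
  list(candidates = candidates, n_input = length(merged),
       n_removed = sum(hit))
}

# Distances from each peak center to a span's two ends.
# left end = span start coordinate, right end = span end coordinate.
.strand_from_peaks <- function(span_start, span_end, centers,
                               max_center_dist) {
  if (length(centers) == 0L) return("*")
  dl <- abs(centers - span_start)
  dr <- abs(centers - span_end)
  dmin <- pmin(dl, dr)
  qual <- which(dmin <= max_center_dist)
  if (length(qual) == 0L) return("*")
  best <- qual[order(dmin[qual], centers[qual])][1L]
  if (dl[best] < dr[best]) "+" else if (dr[best] < dl[best]) "-" else "*"
}

#' Infer transcript strand from peak-center position
#'
#' Among peaks whose center lies within `max_center_dist` bp of either span
#' end, the peak with the center nearest an end decides: strictly nearer the
#' left (smaller-coordinate) end means forward, strictly nearer the right end
#' means reverse, and an equidistant center or no qualifying peak yields
#' unknown. Ties between equally near peaks are broken by the smaller center
#' coordinate.
#'
#' @param candidate A `transcript_model` (or `genomic_interval`) giving the
#'   span.
#' @param peaks A `peak_set` from the supporting tissue.
#' @param max_center_dist Maximum center-to-end distance in bp (default
#'   2000).
#' @return `"+"`, `"-"` or `"*"`.
#' @export
assign_strand <- function(candidate, peaks, max_center_dist = 2000) {
  if (inherits(candidate, "transcript_model")) {
    sp <- tx_span(candidate)
  } else sp <- candidate
  centers <- peaks$center[peaks$chrom == sp$chrom]
  .strand_from_peaks(sp$start, sp$end, centers, max_center_dist)
}

#' Per-tissue H3K4me3 support for candidate transcripts
#'
#' A candidate is supported in a tissue iff some peak of that tissue overlaps
#' its span by >= 1 bp, or has its center within `max_center_dist` bp of
#' either span end. Tissues are evaluated independently; `supported_any` is
#' the union over tissues. A per-tissue strand call (see [assign_strand()])
#' and a consensus strand (conflicting tissue calls give unknown) are
#' recorded alongside.
#'
#' @param candidates List of `transcript_model`s from [subtract_known()].
#' @param peaksets Named list of `peak_set`s, one per tissue; names are the
#'   tissue labels and must be distinct.
#' @param max_center_dist Center-to-end distance threshold in bp.
#' @return A `support_table` data.table with one row per candidate: span
#'   columns, `placement`, one `support_<tissue>` and `strand_<tissue>`
#'   column per tissue, `supported_any`, `consensus_strand` and
#'   `specificity` (see [label_tissue_specificity()]).
#' @export
peak_cooccurrence <- function(candidates, peaksets, max_center_dist = 2000) {
  tissues <- names(peaksets)
  if (is.null(tissues) || any(tissues == "") || anyDuplicated(tissues))
    stop("peaksets must carry distinct, non-empty tissue labels")
  n <- length(candidates)
  if (length(peaksets) == 0L) stop("at least one tissue peak set is required")
  tab <- data.table(
    id = vapply(candidates, `[[`, "", "id"),
    chrom = vapply(candidates, `[[`, "", "chrom"),
    start = vapply(candidates, function(t) t$exons$start[1L], 0),
    end = vapply(candidates, function(t) t$exons$end[nrow(t$exons)], 0),
    exon_count = vapply(candidates, function(t) nrow(t$exons), 0L),
    placement = vapply(candidates, function(t)
      if (is.null(t$placement)) NA_character_ else t$placement, "")
  )
  strand_calls <- matrix("*", n, length(tissues),
                         dimnames = list(NULL, tissues))
  for (tis in tissues) {
    pk <- peaksets[[tis]]
    supp <- logical(n)
    for (i in seq_len(n)) {
      s <- tab$start[i]; e <- tab$end[i]
      sub <- pk[pk$chrom == tab$chrom[i]]
      if (nrow(sub) == 0L) next
      span_ov <- any(sub$start < e & sub$end > s)
      dmin <- pmin(abs(sub$center - s), abs(sub$center - e))
      near <- any(dmin <= max_center_dist)
      supp[i] <- span_ov || near
      if (supp[i])
        strand_calls[i, tis] <- .strand_from_peaks(s, e, sub$center,
                                                   max_center_dist)
    }
    set(tab, j = paste0("support_", tis), value = supp)
  }
  supp_mat <- matrix(FALSE, n, length(tissues), dimnames = list(NULL, tissues))
  for (tis in tissues) supp_mat[, tis] <- tab[[paste0("support_", tis)]]
  set(tab, j = "supported_any", value = rowSums(supp_mat) > 0L)
  for (tis in tissues)
    set(tab, j = paste0("strand_", tis), value = strand_calls[, tis])
  consensus <- vapply(seq_len(n), function(i) {
    known <- setdiff(unique(strand_calls[i, supp_mat[i, ], drop = TRUE]), "*")
    if (length(known) == 1L) known else "*"
  }, "")
  set(tab, j = "consensus_strand", value = if (n) consensus else character())
  tab <- label_tissue_specificity(tab)
  structure(tab, class = c("support_table", class(tab)), tissues = tissues,
            max_center_dist = max_center_dist)
}

#' Label tissue specificity of supported candidates
#'
#' `all-tissues` when every tissue supports the candidate, `single-tissue`
#' when exactly one does, `none` when none does (such candidates are dropped
#' from the final novel set), `subset` otherwise.
#'
#' @param table A `support_table` (or data.table with `support_<tissue>`
#'   logical columns).
#' @return The table with a `specificity` column added/updated.
#' @export
label_tissue_specificity <- function(table) {
  supp_cols <- grep("^support_", names(table), value = TRUE)
  k <- Reduce(`+`, lapply(supp_cols, function(cl) as.integer(table[[cl]])))
  lab <- ifelse(k == 0L, "none",
         ifelse(k == length(supp_cols), "all-tissues",
         ifelse(k == 1L, "single-tissue", "subset")))
  if (is.data.table(table)) set(table, j = "specificity", value = lab)
  else table$specificity <- lab
  table
}

#' Run the full novel-transcript discovery chain in memory
#'
#' Convenience wrapper: [merge_assemblies()] on the per-sample assemblies,
#' [subtract_known()] against the reference annotation, [peak_cooccurrence()]
#' against the per-tissue peak sets, consensus strand assignment and
#' tissue-specificity labels. The final novel set is the candidates with
#' `supported_any`, carrying their consensus strand.
#'
#' @param assemblies List (per sample) of transcript-model lists.
#' @param known Reference [annotation()].
#' @param peaksets Named list of per-tissue `peak_set`s.
#' @param max_center_dist Center-to-end distance threshold in bp.
#' @return List with `merged`, `candidates`, `support` (the support table),
#'   `novel` (final transcript list, strands applied) and `counts` (named
#'   per-stage counts).
#' @export
discover_novel <- function(assemblies, known, peaksets,
                           max_center_dist = 2000) {
  merged <- merge_assemblies(assemblies)
  sub <- subtract_known(merged, known)
  support <- peak_cooccurrence(sub$candidates, peaksets, max_center_dist)
  keep <- which(support$supported_any)
  novel <- sub$candidates[keep]
  for (j in seq_along(keep))
    novel[[j]]$strand <- support$consensus_strand[keep[j]]
  counts <- c(
    n_input_transcripts = sum(vapply(assemblies, length, 0L)),
    n_merged = length(merged),
    n_candidates = length(sub$candidates),
    stats::setNames(
      vapply(grep("^support_", names(support), value = TRUE),
             function(cl) sum(support[[cl]]), 0L),
      sub("^support_", "n_supported_", grep("^support_", names(support),
                                            value = TRUE))),
    n_novel = length(novel)
  )
  list(merged = merged, candidates = sub$candidates, support = support,
       novel = novel, counts = counts)
}
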