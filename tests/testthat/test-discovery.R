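mk <- function(id, starts, ends, strand = "*", chrom = "chr1", samples = id)
  transcript_model(id, chrom, data.frame(start = starts, end = ends),
                   strand = strand, source_samples = samples)

test_that("overlapping transcripts merge with exon-union coalescing", {
  m <- merge_assemblies(list(
    list(mk("s1a", c(100, 500), c(300, 700))),
    list(mk("s2a", 250, 350))))
  expect_length(m, 1)
  expect_equal(m[[1]]$exons, data.frame(start = c(100, 500),
                                        end = c(350, 700)))
  expect_equal(sort(m[[1]]$members), c("s1a", "s2a"))
  expect_equal(sort(m[[1]]$source_samples), c("s1a", "s2a"))

  # non-overlapping stay separate; merging output with itself is the identity
  m2 <- merge_assemblies(list(list(mk("a", 100, 200), mk("b", 300, 400))))
  expect_length(m2, 2)
  again <- merge_assemblies(list(m))
  expect_length(again, 1)
  expect_equal(again[[1]]$exons, m[[1]]$exons)
})

test_that("merging is idempotent and order-invariant on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    asm <- lapply(1:4, function(s)
      lapply(1:15, function(i) rand_tx(sprintf("s%d_t%02d", s, i))))
    m1 <- merge_assemblies(asm)
    m2 <- merge_assemblies(asm[sample(length(asm))])
    members1 <- canon_members(lapply(m1, `[[`, "members"))
    members2 <- canon_members(lapply(m2, `[[`, "members"))
    expect_equal(members1, members2)
    # idempotence: exon structures unchanged by a second merge
    m3 <- merge_assemblies(list(m1))
    expect_equal(lapply(m3, `[[`, "exons"), lapply(m1, `[[`, "exons"))
  }
})

test_that("merge clusters equal igraph single-linkage components", {
  set.seed(32)
  for (rep in 1:10) {
    txs <- lapply(1:30, function(i) rand_tx(sprintf("t%02d", i)))
    m <- merge_assemblies(list(txs))
    expect_equal(canon_members(lapply(m, `[[`, "members")),
                 canon_members(o_merge_members(txs)))
  }
})

test_that("opposite known strands never merge; unknown bridges are split", {
  # + and - overlapping directly: stay apart
  m <- merge_assemblies(list(list(mk("p", 100, 400, "+"),
                                  mk("q", 200, 500, "-"))))
  expect_length(m, 2)
  expect_equal(sort(vapply(m, `[[`, "", "strand")), c("+", "-"))
  # unknown-strand bridge between + and -: component is split by strand,
  # the unknown member staying with the forward side
  m2 <- merge_assemblies(list(list(mk("p", 100, 400, "+"),
                                   mk("u", 300, 700, "*"),
                                   mk("q", 600, 900, "-"))))
  expect_length(m2, 2)
  members <- canon_members(lapply(m2, `[[`, "members"))
  expect_equal(members, canon_members(list(c("p", "u"), "q")))
})

known_ann <- function() {
  tx <- transcript_model("kg.t1", "chr1",
                         data.frame(start = c(1000, 2500, 4000),
                                    end = c(2000, 2600, 5000)),
                         strand = "+")
  annotation(list(gene_model("kg", list(tx))), c(chr1 = 20000))
}

test_that("subtraction keeps only zero-exonic-overlap transcripts", {
  known <- known_ann()
  merged <- list(mk("inA", 1500, 1600),      # inside a known exon
                 mk("edge", 2000, 2450),     # book-ended: overlap 0, intronic
                 mk("far", 8000, 9000))      # intergenic
  res <- subtract_known(merged, known)
  ids <- vapply(res$candidates, `[[`, "", "id")
  expect_equal(sort(ids), c("edge", "far"))
  expect_equal(res$n_removed, 1L)
  flags <- vapply(res$candidates, `[[`, "", "placement")
  expect_equal(flags[ids == "edge"][[1]], "intronic")
  expect_equal(flags[ids == "far"][[1]], "intergenic")
})

test_that("self-subtraction removes every known transcript", {
  set.seed(33)
  txs <- lapply(1:25, function(i) rand_tx(sprintf("t%02d", i)))
  ann <- annotation_from_transcripts(txs, c(chr1 = 60000, chr2 = 60000))
  res <- subtract_known(txs, ann)
  expect_length(res$candidates, 0)
  expect_equal(res$n_removed, 25L)
})

test_that("peak co-occurrence uses span overlap OR center-near-end", {
  cand <- list(mk("c1", 10000, 12000))
  # peak inside the span
  t1 <- peak_cooccurrence(cand, list(leaf = make_peaks("chr1", 11000, 11500)))
  expect_true(t1$support_leaf)
  # center 8850, 1150 bp from the left end: supported
  t2 <- peak_cooccurrence(cand, list(leaf = make_peaks("chr1", 8500, 9200)))
  expect_true(t2$support_leaf)
  # center 14750, 2750 bp away: not supported
  t3 <- peak_cooccurrence(cand, list(leaf = make_peaks("chr1", 14500, 15000)))
  expect_false(t3$support_leaf)
  expect_false(t3$supported_any)
  # tissues independent; supported_any is their union
  t4 <- peak_cooccurrence(cand, list(
    leaf = make_peaks("chr1", 14500, 15000, tissue = "leaf"),
    stem = make_peaks("chr1", 11000, 11500, tissue = "stem")))
  expect_false(t4$support_leaf)
  expect_true(t4$support_stem)
  expect_true(t4$supported_any)
  expect_error(peak_cooccurrence(cand, stats::setNames(
    list(make_peaks("chr1", 1, 10), make_peaks("chr1", 1, 10)),
    c("leaf", "leaf"))), "distinct")
})

test_that("strand rule: nearest qualifying center decides, ties unknown", {
  span <- transcript_model("c", "chr1", data.frame(start = 10000, end = 12000))
  expect_equal(assign_strand(span, make_peaks("chr1", 9300, 9700)), "+")
  expect_equal(assign_strand(span, make_peaks("chr1", 12200, 12600)), "-")
  # center 11000 equidistant from both ends -> unknown
  expect_equal(assign_strand(span, make_peaks("chr1", 10800, 11200)), "*")
  # no qualifying center -> unknown
  expect_equal(assign_strand(span, make_peaks("chr1", 14500, 15000)), "*")
  # the nearest of several qualifying peaks wins
  expect_equal(assign_strand(span, make_peaks("chr1", c(9300, 12300),
                                              c(9700, 12700))), "+")
})

test_that("consensus strand: conflicting tissue calls give unknown", {
  cand <- list(mk("c1", 10000, 12000))
  tab <- peak_cooccurrence(cand, list(
    leaf = make_peaks("chr1", 9300, 9700, tissue = "leaf"),
    stem = make_peaks("chr1", 12200, 12600, tissue = "stem")))
  expect_equal(tab$strand_leaf, "+")
  expect_equal(tab$strand_stem, "-")
  expect_equal(tab$consensus_strand, "*")
  tab2 <- peak_cooccurrence(cand, list(
    leaf = make_peaks("chr1", 9300, 9700, tissue = "leaf"),
    stem = make_peaks("chr1", 9200, 9600, tissue = "stem")))
  expect_equal(tab2$consensus_strand, "+")
})

test_that("tissue-specificity labels count supporting tissues", {
  tab <- data.frame(support_leaf = c(TRUE, TRUE, FALSE, TRUE),
                    support_stem = c(TRUE, FALSE, FALSE, TRUE),
                    support_root = c(TRUE, FALSE, FALSE, FALSE))
  out <- label_tissue_specificity(tab)
  expect_equal(out$specificity,
               c("all-tissues", "single-tissue", "none", "subset"))
})
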