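test_that("the worked single-gene partition yields the expected class bp", {
  part <- build_region_partition(toy_annotation(), promoter_bp = 2000)
  bp <- tapply(part$end - part$start, part$label, sum)
  expect_equal(bp[["promoter"]], 2000)
  expect_equal(bp[["utr5"]], 200)
  expect_equal(bp[["coding_exon"]], 900)
  expect_equal(bp[["utr3"]], 500)
  expect_equal(bp[["intron"]], 1400)
  expect_equal(bp[["intergenic"]], 5000)
  expect_equal(sum(bp), 10000)

  fr <- region_fractions(part)
  expect_equal(unname(fr[c("intergenic", "promoter", "intron", "coding_exon",
                           "utr3", "utr5")]),
               c(50, 20, 14, 9, 5, 2))
  expect_equal(sum(fr), 100, tolerance = 1e-9)
})

test_that("empty annotation partitions to 100% intergenic", {
  ann <- annotation(list(), c(chr1 = 5000, chr2 = 3000))
  part <- build_region_partition(ann)
  expect_equal(unname(region_fractions(part)["intergenic"]), 100)
  expect_equal(sum(part$end - part$start), 8000)
})

test_that("partition equals brute-force per-base labeling on random annotations", {
  set.seed(41)
  for (rep in 1:40) {
    ann <- rand_annotation(n_genes = sample(2:12, 1),
                           chrom_len = sample(20000:50000, 1))
    part <- build_region_partition(ann, promoter_bp = 2000)
    got <- expand_partition(part)
    want <- o_partition_bases(ann, promoter_bp = 2000)
    for (cm in names(want)) expect_identical(got[[cm]], want[[cm]])
    expect_equal(sum(part$end - part$start), sum(ann$chrom_sizes))
  }
})

test_that("gene order does not change the fractions", {
  set.seed(42)
  ann <- rand_annotation(n_genes = 8)
  perm <- annotation(ann$genes[sample(length(ann$genes))], ann$chrom_sizes)
  expect_equal(region_fractions(build_region_partition(ann)),
               region_fractions(build_region_partition(perm)))
})

test_that("peak bp distribute across classes and match the per-base tally", {
  part <- build_region_partition(toy_annotation())
  pd <- peak_region_distribution(make_peaks("chr1", 1500, 2500), part)
  expect_equal(unname(pd[c("promoter", "utr5", "coding_exon")]),
               c(50, 20, 30))
  expect_equal(sum(pd), 100, tolerance = 1e-9)
  pd2 <- peak_region_distribution(make_peaks("chr1", 7000, 9000), part)
  expect_equal(unname(pd2["intergenic"]), 100)
  # random peaks vs per-base oracle
  set.seed(43)
  ann <- rand_annotation(n_genes = 8)
  part <- build_region_partition(ann)
  bases <- o_partition_bases(ann)
  pk <- make_peaks(sample(names(ann$chrom_sizes), 20, replace = TRUE),
                   start = s <- sample.int(40000, 20),
                   end = s + sample(200:3000, 20, replace = TRUE))
  pd3 <- peak_region_distribution(pk, part)
  tally <- table(unlist(lapply(seq_len(nrow(pk)), function(i)
    bases[[pk$chrom[i]]][(pk$start[i] + 1):pk$end[i]])))
  want <- 100 * as.numeric(tally) / sum(tally)
  expect_equal(unname(pd3[names(tally)]), want, tolerance = 1e-9)
  # clipping beyond bounds warns
  expect_warning(peak_region_distribution(
    make_peaks("chrA", 49500, 50500), part), "clipped")
})

test_that("peak-to-gene association uses body plus strand-aware upstream", {
  fwd <- annotation(list(gene_model("g", list(
    transcript_model("g.t", "chr1", data.frame(start = 5000, end = 8000),
                     strand = "+")))), c(chr1 = 20000))
  expect_equal(associate_peaks_to_genes(
    make_peaks("chr1", 3500, 4200), fwd)$genes, "g")   # upstream window
  expect_equal(associate_peaks_to_genes(
    make_peaks("chr1", 1000, 1500), fwd)$n_genes, 0L)  # too far upstream
  expect_equal(associate_peaks_to_genes(
    make_peaks("chr1", 8100, 8400), fwd)$n_genes, 0L)  # downstream
  rev <- annotation(list(gene_model("g", list(
    transcript_model("g.t", "chr1", data.frame(start = 5000, end = 8000),
                     strand = "-")))), c(chr1 = 20000))
  expect_equal(associate_peaks_to_genes(
    make_peaks("chr1", 8100, 8400), rev)$genes, "g")   # upstream of rev TSS
  expect_equal(associate_peaks_to_genes(
    make_peaks("chr1", 3500, 4200), rev)$n_genes, 0L)
})

test_that("association equals a brute-force all-pairs scan on random inputs", {
  set.seed(44)
  for (rep in 1:5) {
    ann <- rand_annotation(n_genes = 10)
    pk <- make_peaks(sample(names(ann$chrom_sizes), 30, replace = TRUE),
                     start = s <- sample.int(45000, 30),
                     end = s + sample(100:2000, 30, replace = TRUE))
    got <- associate_peaks_to_genes(pk, ann, upstream_bp = 2000)$genes
    g <- ann$gene_table
    want <- sort(unique(unlist(lapply(seq_len(nrow(g)), function(i) {
      ws <- if (g$strand[i] == "-") g$start[i] else max(g$tss[i] - 2000, 0)
      we <- if (g$strand[i] == "-") g$tss[i] + 2000 else g$end[i]
      hit <- any(pk$chrom == g$chrom[i] & pk$start < we & pk$end > ws)
      if (hit) g$gene[i] else NULL
    }))))
    expect_equal(got, if (is.null(want)) character() else want)
  }
})

test_that("per-million normalization scales values and total area exactly", {
  p <- tempfile()
  writeLines(c("chr1\t0\t100\t30", "chr1\t200\t300\t12"), p)
  trk <- read_bedgraph(p)
  norm <- normalize_per_million(trk, 30e6)
  expect_equal(coverage_value(norm, "chr1", 50), 1.0)
  expect_equal(coverage_value(norm, "chr1", 150), 0)
  area <- function(t) sum((t$end - t$start) * t$value)
  expect_equal(area(norm), area(trk) * 1e6 / 30e6)
  expect_equal(attr(norm, "normalization_state"), "per-million")
  expect_error(normalize_per_million(norm, 30e6), "already normalized")
  expect_error(normalize_per_million(trk, 0), "positive")
})

const_track <- function(value, len = 50000) {
  dt <- data.table::data.table(chrom = "chr1", start = 0, end = len,
                               value = value)
  structure(dt, class = c("coverage_track", class(dt)),
            normalization_state = "raw")
}

test_that("meta-gene profile of constant coverage is constant", {
  genes <- data.frame(chrom = "chr1", start = c(5000, 20000),
                      end = c(9000, 21000), strand = c("+", "-"))
  mp <- metagene_profile(const_track(2), genes)
  expect_length(mp$values, 20 + 100 + 20)
  expect_equal(mp$values, rep(2, 140))
  mp0 <- metagene_profile(const_track(0), genes)
  expect_equal(mp0$values, rep(0, 140))
})

test_that("profile bins equal brute-force per-base means, with strand flip", {
  # a signal step inside the body of a forward gene
  p <- tempfile()
  writeLines(c("chr1\t5000\t7000\t1", "chr1\t7000\t9000\t5"), p)
  trk <- read_bedgraph(p)
  g_fwd <- data.frame(chrom = "chr1", start = 5000, end = 9000, strand = "+")
  mp <- metagene_profile(trk, g_fwd, flank_bp = 1000, body_bins = 100,
                         flank_bin_bp = 50)
  # body bin k covers [5000 + 40(k-1), 5000 + 40k)
  want_body <- vapply(1:100, function(k)
    mean(coverage_value(trk, "chr1", (5000 + 40 * (k - 1)):(5000 + 40 * k - 1))),
    0)
  expect_equal(mp$values[21:120], want_body)
  expect_equal(mp$values[1:20], rep(0, 20))    # upstream flank uncovered
  # the same gene on the reverse strand reads 5'->3' from the right
  g_rev <- g_fwd; g_rev$strand <- "-"
  mp_rev <- metagene_profile(trk, g_rev)
  expect_equal(mp_rev$values, rev(mp$values))
})

test_that("bodies shorter than the bin count use fractional-base means", {
  p <- tempfile()
  writeLines("chr1\t1000\t1050\t4", p)
  trk <- read_bedgraph(p)
  g <- data.frame(chrom = "chr1", start = 1000, end = 1050, strand = "+")
  mp <- metagene_profile(trk, g, body_bins = 100)
  expect_equal(mp$values[21:120], rep(4, 100))
})

test_that("expression-quantile grouping follows the remainder-to-lowest rule", {
  set.seed(45)
  genes <- lapply(1:25, function(i) gene_model(sprintf("g%02d", i), list(
    transcript_model(sprintf("g%02d.t", i), "chr1",
                     data.frame(start = 1000 * i, end = 1000 * i + 800),
                     strand = "+"))))
  ann <- annotation(genes, c(chr1 = 50000))
  fpkm <- c(stats::runif(20, 0.5, 50), rep(0, 5))
  m <- matrix(fpkm, ncol = 1, dimnames = list(names(ann$genes), "s1"))
  out <- profiles_by_expression_quantile(const_track(1), ann, m, "s1",
                                         n_quantiles = 9)
  expect_equal(unname(out$sizes), c(3, 3, 2, 2, 2, 2, 2, 2, 2))
  expect_length(out$membership$not_expressed, 5)
  # groups ordered by expression, lowest first
  gmax <- vapply(out$membership[paste0("Q", 1:9)],
                 function(ids) max(m[ids, "s1"]), 0)
  gmin <- vapply(out$membership[paste0("Q", 1:9)],
                 function(ids) min(m[ids, "s1"]), 0)
  expect_true(all(gmax[-9] <= gmin[-1]))
  # 9 distinct expressed genes -> nine singletons ordered by FPKM
  m9 <- matrix(sort(stats::runif(9, 1, 10)), ncol = 1,
               dimnames = list(names(ann$genes)[1:9], "s1"))
  out9 <- profiles_by_expression_quantile(const_track(1), ann, m9, "s1")
  expect_equal(unname(out9$sizes), rep(1, 9))
  # all genes at zero: only the not-expressed profile
  m0 <- matrix(0, nrow = 25, ncol = 1,
               dimnames = list(names(ann$genes), "s1"))
  out0 <- profiles_by_expression_quantile(const_track(1), ann, m0, "s1")
  expect_true(all(vapply(out0$profiles, is.null, TRUE)))
  expect_equal(out0$not_expressed$n_genes, 25)
})

test_that("TSS signal increases with expression quantile on gradient coverage", {
  fx <- generate_fixture(synth_config(seed = 5, n_novel = 20,
                                      n_known_genes = 90, n_chroms = 2,
                                      chrom_length = 8e5, n_samples = 3),
                         dir = tempfile())
  out <- profiles_by_expression_quantile(fx$tracks$leaf, fx$known, fx$expr,
                                         "leaf_s01", n_quantiles = 9)
  tss_bin <- 21  # first body bin, 5'-most
  v <- vapply(out$profiles, function(p) p$values[tss_bin], 0)
  expect_true(all(diff(v) >= 0))
})
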