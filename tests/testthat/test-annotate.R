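# minimal hand-built gene model helper
toy_genes <- function(symbol, chrom, start, end, strand,
                      thick_frac = c(0.25, 0.75), n_exon = 2) {
  n <- length(symbol)
  g <- data.frame(chrom = chrom, start = start, end = end,
                  symbol = symbol, strand = strand,
                  stringsAsFactors = FALSE)
  g$thick_start <- round(start + thick_frac[1] * (end - start))
  g$thick_end <- round(start + thick_frac[2] * (end - start))
  len <- end - start
  g$exon_starts <- Map(function(s, l) {
    if (n_exon == 1) s else c(s, s + round(0.6 * l))
  }, start, len)
  g$exon_ends <- Map(function(s, l) {
    if (n_exon == 1) s + l else c(s + round(0.3 * l), s + l)
  }, start, len)
  g
}

test_that("CpG shores and shelves flank islands with fixed precedence", {
  cl <- c(c1 = 1e6)
  ctx <- cpg_flanks(genomic_intervals("c1", 10000, 11000), cl)
  expect_equal(ctx$shores,
               genomic_intervals(c("c1", "c1"), c(8000, 11000),
                                 c(10000, 13000)))
  expect_equal(ctx$shelves,
               genomic_intervals(c("c1", "c1"), c(6000, 13000),
                                 c(8000, 15000)))

  # island at the chromosome start: left flanks clipped away
  ctx0 <- cpg_flanks(genomic_intervals("c1", 0, 500), cl)
  expect_equal(ctx0$shores, genomic_intervals("c1", 500, 2500))
  expect_equal(ctx0$shelves, genomic_intervals("c1", 2500, 4500))

  expect_error(cpg_flanks(genomic_intervals("c1", 999900, 1000200), cl),
               "outside chromosome bounds")
})

test_that("flank construction matches a per-base labelling oracle", {
  # two islands 3 kb apart: inter-island region partitioned shore-first
  cases <- list(
    genomic_intervals(c("c1", "c1"), c(20000, 24000), c(21000, 25000)),
    genomic_intervals("c1", 0, 800))
  set.seed(17)
  for (rep in 1:5) {
    st <- sort(sample(seq(0, 44000, by = 400), 4))
    cases[[length(cases) + 1]] <-
      genomic_intervals("c1", st, st + sample(200:1500, 4))
  }
  for (isl in cases) {
    isl <- merge_intervals(isl)
    L <- 50000
    ctx <- cpg_flanks(isl, c(c1 = L))
    lab <- oracle_base_labels(isl, L)
    expect_equal(coverage_vector(ctx$islands, L), lab == "island")
    expect_equal(coverage_vector(ctx$shores, L), lab == "shore")
    expect_equal(coverage_vector(ctx$shelves, L), lab == "shelf")
    # pairwise disjoint by construction
    expect_false(any(coverage_vector(ctx$islands, L) &
                       coverage_vector(ctx$shores, L)))
    expect_false(any(coverage_vector(ctx$shelves, L) &
                       (coverage_vector(ctx$islands, L) |
                          coverage_vector(ctx$shores, L))))
  }
})

test_that("window tiling covers chromosomes, final partial tile kept", {
  w <- make_windows(c(c1 = 1500), 500)
  expect_equal(nrow(w), 3L)
  w2 <- make_windows(c(c1 = 1501), 500)
  expect_equal(nrow(w2), 4L)
  expect_equal(interval_width(w2)[4], 1L)
  cl <- c(c1 = 1501, c2 = 999, c3 = 2000)
  expect_equal(nrow(make_windows(cl, 500)), sum(ceiling(cl / 500)))
})

test_that("window flags equal a brute-force overlap scan", {
  w <- make_windows(c(c1 = 25000), 500)  # 50 windows
  feats <- list(whole = genomic_intervals("c1", 0, 25000),
                point = genomic_intervals("c1", 12345, 12346))
  set.seed(29)
  feats$rand <- random_intervals(12, max_pos = 24000, max_width = 900)
  g <- flag_windows(w, feats)
  expect_true(all(g$whole))
  expect_equal(sum(g$point), 1L)
  expect_true(g$point[floor(12345 / 500) + 1])
  for (feat in names(feats)) {
    brute <- vapply(seq_len(nrow(w)), function(i)
      any(vapply(seq_len(nrow(feats[[feat]])), function(j)
        oracle_overlap(w$chrom[i], w$start[i], w$end[i],
                       feats[[feat]]$chrom[j], feats[[feat]]$start[j],
                       feats[[feat]]$end[j]), logical(1))), logical(1))
    expect_equal(g[[feat]], brute)
  }
})

test_that("DMR classification follows the documented precedence", {
  g <- toy_genes(c("FWD", "REV"), "c1", c(50000, 100000),
                 c(60000, 110000), c("+", "-"))
  cls <- function(s, e) classify_dmr(genomic_intervals("c1", s, e), g)
  # 500 bp upstream of the + strand TSS at 50000
  expect_equal(cls(49000, 50000), "Promoter (<=1 kb)")
  expect_equal(cls(47500, 48500), "Promoter (1-2 kb)")
  expect_equal(cls(46500, 47500), "Promoter (2-3 kb)")
  # minus-strand TSS at 110000: upstream means larger coordinates
  expect_equal(cls(110200, 111000), "Promoter (<=1 kb)")
  # first exon before the coding start is 5' UTR (+ strand)
  expect_equal(cls(50100, 50300), "5' UTR")
  # past coding end, still exonic (+ strand): 3' UTR
  expect_equal(cls(59200, 59800), "3' UTR")
  # coding part of an exon
  expect_equal(cls(52600, 52800), "Exon")
  # between exon1 end (53000) and exon2 start (56000): first intron
  expect_equal(cls(54000, 54500), "1st Intron")
  # minus strand: the first intron is the one nearest the TSS
  expect_equal(cls(104000, 104100), "1st Intron")
  expect_equal(cls(44000, 45000), "Distal Intergenic")
  expect_equal(cls(60100, 61000), "Downstream (<=3 kb)")
  expect_equal(classify_dmr(genomic_intervals("c9", 0, 100), g),
               "Distal Intergenic")
})

test_that("nearest gene is chosen by TSS distance with tie rule", {
  g1 <- toy_genes("ONLY", "c1", 5000, 8000, "+")
  ng <- nearest_gene(genomic_intervals("c1", 100, 200), g1)
  expect_equal(ng$symbol, "ONLY")

  # equidistant TSSs: lexicographically smaller symbol wins
  g2 <- toy_genes(c("GENE_B", "GENE_A"), "c1", c(1000, 9000),
                  c(3000, 11000), c("+", "+"))
  mid <- nearest_gene(genomic_intervals("c1", 4999, 5001), g2)
  expect_equal(mid$symbol, "GENE_A")

  # inside a transcript the distance is zero
  inside <- nearest_gene(genomic_intervals("c1", 1500, 1600), g2)
  expect_equal(inside$symbol, "GENE_B")

  # 20-gene fixture vs exhaustive scan
  set.seed(61)
  starts <- sort(sample(seq(0, 9e5, by = 1e3), 20))
  g20 <- toy_genes(sprintf("G%02d", sample(20)), "c1", starts,
                   starts + 800, sample(c("+", "-"), 20, TRUE))
  dmrs <- random_intervals(30, max_pos = 9e5, max_width = 2000)
  got <- nearest_gene(dmrs, g20)
  tss <- ifelse(g20$strand == "+", g20$start, g20$end - 1)
  for (i in seq_len(nrow(dmrs))) {
    m <- floor((dmrs$start[i] + dmrs$end[i]) / 2)
    d <- ifelse(m >= g20$start & m < g20$end, 0, abs(tss - m))
    expect_equal(got$symbol[i],
                 g20$symbol[order(d, g20$symbol)][1])
  }
  expect_error(nearest_gene(dmrs, g20[0, ]), "empty gene model")
})

test_that("category percentages sum to 100 and match direct counting", {
  one <- data.frame(annotation = rep("Exon", 4))
  expect_equal(unname(category_percentages(one)), 100)

  ptb <- published_dmr_table("ptb")
  pct <- category_percentages(ptb)
  expect_equal(sum(pct), 100)
  expect_equal(names(pct)[1], "Distal Intergenic")
  expect_equal(unname(pct["Distal Intergenic"]), 100 * 10 / 21)
  # all published annotation strings are canonical categories
  canon <- c("Promoter (<=1 kb)", "Promoter (1-2 kb)", "Promoter (2-3 kb)",
             "5' UTR", "3' UTR", "Exon", "1st Intron", "Intron",
             "Downstream (<=3 kb)", "Distal Intergenic")
  expect_true(all(ptb$annotation %in% canon))
  expect_true(all(published_dmr_table("ga")$annotation %in% canon))
})
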