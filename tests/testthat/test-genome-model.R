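si1 <- GenomeInfoDb::Seqinfo("c1", 1e6)

test_that("expand_to_window does the padded-span and centred arithmetic", {
  g <- GRanges("c1", IRanges(60001, 62000), "+")
  w <- expand_to_window(g, window_spec("gene_span_pad", pad_bp = 5e4), si1)
  expect_equal(start(w), 10001)
  expect_equal(end(w), 112000)
  expect_false(w$clipped)

  g2 <- GRanges("c1", IRanges(10001, 12000))
  w2 <- expand_to_window(g2, window_spec("gene_span_pad", pad_bp = 5e4), si1)
  expect_equal(start(w2), 1)
  expect_equal(end(w2), 62000)
  expect_true(w2$clipped)

  g3 <- GRanges("c1", IRanges(499001, 501000))
  w3 <- expand_to_window(g3, window_spec("fixed_center", width_bp = 1e5), si1)
  expect_equal(start(w3), 450001)
  expect_equal(end(w3), 550000)
  expect_equal(width(w3), 1e5)

  expect_error(expand_to_window(GRanges("nope", IRanges(1, 10)),
                                window_spec(), si1), "absent")
})

test_that("window_spec validates bin divisibility", {
  expect_error(window_spec(width_bp = 100001, bin_bp = 1000), "divisible")
  expect_error(window_spec(pad_bp = 0), "pad_bp")
})

test_that("coverage_fraction merges overlapping elements before measuring", {
  w <- GRanges("c1", IRanges(1, 100))
  expect_equal(coverage_fraction(w, GRanges("c1", IRanges(1, 50))), 0.5)
  tes <- GRanges("c1", IRanges(c(1, 41), c(60, 100)))
  expect_equal(coverage_fraction(w, tes), 1.0)
  # order invariance and split invariance
  expect_equal(coverage_fraction(w, rev(tes)), 1.0)
  split_tes <- GRanges("c1", IRanges(c(1, 31, 41), c(30, 60, 100)))
  expect_equal(coverage_fraction(w, split_tes), 1.0)
  # other-contig TEs never count
  expect_equal(suppressWarnings(
    coverage_fraction(w, GRanges("c2", IRanges(1, 100)))), 0)
})

test_that("coverage_fraction agrees with the per-base mask oracle", {
  set.seed(42)
  for (rep in 1:200) {
    L <- sample(2000:10000, 1)
    ws <- sample(seq_len(L - 500), 1)
    we <- ws + sample(100:500, 1)
    n_te <- sample(0:50, 1)
    te <- if (n_te == 0) GRanges() else {
      ts <- sample(seq_len(L), n_te, replace = TRUE)
      GRanges("c1", IRanges(ts, pmin(ts + sample(10:400, n_te,
                                                 replace = TRUE) - 1L, L)))
    }
    w <- GRanges("c1", IRanges(ws, we))
    got <- coverage_fraction(w, te)
    want <- oracle_coverage(ws, we, start(te), end(te))
    expect_equal(got, want)
    # Rle fast path agrees with the GRanges path
    cvg <- te_coverage(te, c(c1 = L))
    expect_equal(coverage_fraction(w, cvg), want)
  }
})

test_that("binned_coverage is consistent with per-bin coverage_fraction", {
  set.seed(7)
  w <- GRanges("c1", IRanges(1001, 11000))
  te <- GRanges("c1", IRanges(sample(500:11500, 40, replace = TRUE),
                              width = sample(50:900, 40, replace = TRUE)))
  spec <- window_spec(bin_bp = 500)
  v <- binned_coverage(w, "+", te, spec)
  expect_length(v, 20)
  for (i in seq_along(v)) {
    bin <- GRanges("c1", IRanges(1001 + (i - 1) * 500, width = 500))
    expect_equal(v[i], coverage_fraction(bin, te))
  }
  # bin mass accounts for every covered base exactly
  expect_equal(sum(v) * 500, coverage_fraction(w, te) * width(w))
})

test_that("binned_coverage strand flip is exact and errors on bad widths", {
  set.seed(8)
  w <- GRanges("c1", IRanges(2001, 12000))
  te <- GRanges("c1", IRanges(sample(1500:12500, 30, replace = TRUE),
                              width = sample(20:700, 30, replace = TRUE)))
  spec <- window_spec(bin_bp = 1000)
  plus <- binned_coverage(w, "+", te, spec)
  minus <- binned_coverage(w, "-", te, spec)
  expect_identical(minus, rev(plus))
  expect_warning(binned_coverage(w, "*", te, spec), "unstranded")
  expect_error(binned_coverage(GRanges("c1", IRanges(1, 1500)), "+", te,
                               spec), "divisible")
})

test_that("sample_random_windows is reproducible and in-bounds", {
  w1 <- sample_random_windows(si1, 1e4, 50, seed = 9)
  w2 <- sample_random_windows(si1, 1e4, 50, seed = 9)
  expect_identical(w1, w2)
  expect_true(all(start(w1) >= 1 & end(w1) <= 1e6))
  expect_true(all(width(w1) == 1e4))
  expect_length(sample_random_windows(si1, 1e4, 0, seed = 1), 0)
  # a contig exactly as long as the window forces [1, width]
  forced <- sample_random_windows(c(tiny = 5000), 5000, 10, seed = 2)
  expect_true(all(start(forced) == 1 & end(forced) == 5000))
  expect_error(sample_random_windows(c(tiny = 100), 5000, 1), "5000")
})

test_that("window sampling pools eligible positions across contigs", {
  lens <- c(a = 30000, b = 70000)
  w <- 10000
  n <- 10000
  wins <- sample_random_windows(lens, w, n, seed = 11)
  ea <- lens["a"] - w + 1; eb <- lens["b"] - w + 1
  p_a <- ea / (ea + eb)
  ci <- qbinom(c(0.005, 0.995), n, p_a)
  na <- sum(as.character(seqnames(wins)) == "a")
  expect_gte(na, ci[1])
  expect_lte(na, ci[2])
  # start positions are uniform: chi-square over 20 equal classes
  wins1 <- sample_random_windows(c(one = 1e5), 1000, 10000, seed = 12)
  elig <- 1e5 - 1000 + 1
  cls <- cut(start(wins1), breaks = seq(1, elig + 1, length.out = 21),
             include.lowest = TRUE, right = FALSE)
  expect_gt(suppressWarnings(chisq.test(table(cls))$p.value), 0.01)
})

test_that("sampling honours an exclusion mask", {
  mask <- GRanges("c1", IRanges(1, 9e5))
  wins <- sample_random_windows(si1, 1e4, 200, seed = 13, exclude = mask)
  expect_false(any(overlapsAny(wins, mask)))
})

test_that("gene model and TE annotation files round-trip", {
  sim <- quick_sim(21, n_genes = 2, n_pseudogenes = 1, bg = 0.1)
  gff <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(sim$genes, gff)
  back <- read_gene_models(gff)
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(start(back), start(sim$genes))
  expect_equal(as.character(strand(back)), as.character(strand(sim$genes)))
  expect_equal(unname(lapply(back$exons, start)),
               unname(lapply(sim$genes$exons, start)))

  bed <- tempfile(fileext = ".bed")
  write_te_bed(sim$tes, bed)
  tes2 <- read_te_annotations(bed)
  expect_equal(length(tes2), length(sim$tes))
  expect_equal(start(tes2), start(sim$tes))
  expect_equal(tes2$family, sim$tes$family)
  expect_equal(as.character(strand(tes2)), as.character(strand(sim$tes)))
})
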