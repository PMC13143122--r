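test_that("mean_density averages per-window coverage fractions", {
  w <- GRanges("c1", IRanges(c(1, 201), c(100, 300)))
  tes <- GRanges("c1", IRanges(c(1, 201), c(20, 260)))
  expect_equal(mean_density(w, tes), mean(c(0.2, 0.6)))
  expect_equal(mean_density(w, GRanges()), 0)
  expect_error(mean_density(GRanges(), tes), "empty")
  # element-count mode: elements per kb by midpoint containment
  expect_equal(mean_density(w, tes, stat = "count"), mean(c(10, 10)))
})

test_that("a fully covered genome gives a degenerate, honest test", {
  si <- c(c1 = 2e5)
  tes <- GRanges("c1", IRanges(1, 2e5))
  focal <- GRanges("c1", IRanges(5e4 + 1, 6e4))
  enr <- permutation_test(focal, tes, si, n_perm = 99, width = 1e4, seed = 81)
  expect_equal(enr$observed_mean, 1.0)
  expect_equal(unique(enr$null_means), 1.0)
  expect_equal(enr$fold, 1.0)
  expect_equal(enr$empirical_p, 1.0)
})

test_that("an observed mean above every null mean hits the plus-one floor", {
  # TEs only inside the focal window; background empty
  si <- c(c1 = 1e6)
  focal <- GRanges("c1", IRanges(500001, 510000))
  tes <- GRanges("c1", IRanges(seq(500001, 509000, by = 1000), width = 500))
  enr <- permutation_test(focal, tes, si, n_perm = 200, width = 1e4,
                          seed = 82)
  expect_gt(enr$observed_mean, max(enr$null_means))
  expect_equal(enr$empirical_p, 1 / 201)
  expect_gt(enr$empirical_p, 0)
})

test_that("empirical p is monotone non-increasing in the observed mean", {
  set.seed(83)
  si <- c(c1 = 5e5)
  ts <- sample(1:499700, 400)
  tes <- GRanges("c1", IRanges(ts, ts + 299))
  dens <- coverage_fraction(
    GRanges("c1", IRanges(seq(1, 4.9e5, by = 1e4), width = 1e4)), tes)
  lo <- GRanges("c1", IRanges(which.min(dens) * 1e4 - 9999, width = 1e4))
  hi <- GRanges("c1", IRanges(which.max(dens) * 1e4 - 9999, width = 1e4))
  p_lo <- permutation_test(lo, tes, si, n_perm = 99, width = 1e4,
                           seed = 84)$empirical_p
  p_hi <- permutation_test(hi, tes, si, n_perm = 99, width = 1e4,
                           seed = 84)$empirical_p
  expect_lte(p_hi, p_lo)
})

test_that("profiling then averaging equals averaging the per-locus profiles", {
  sim <- quick_sim(85, n_genes = 6, n_pseudogenes = 0, bg = 0.3,
                   contig = 8e5)
  spec <- window_spec("fixed_center", width_bp = 4e4, bin_bp = 1000)
  prof <- density_profile(sim$genes, sim$tes, sim$seqinfo, spec)
  wins <- expand_to_window(sim$genes, spec, sim$seqinfo)
  per_locus <- vapply(seq_along(wins), function(i)
    binned_coverage(wins[i], as.character(strand(sim$genes))[i], sim$tes,
                    spec), numeric(40))
  expect_identical(prof$mean_density, rowMeans(per_locus))
  expect_equal(prof$n_loci, 6)
})

test_that("a constructed downstream TE block peaks at +10 kb for minus genes", {
  si <- c(c1 = 3e5)
  centers <- c(8e4, 15e4, 22e4)
  genes <- GRanges("c1", IRanges(centers - 1000, centers + 999),
                   strand = "-")
  # downstream in gene orientation = genomic left for minus-strand genes
  tes <- GRanges("c1", IRanges(centers - 10000 - 1000, width = 2000))
  prof <- density_profile(genes, tes, si,
                          window_spec("fixed_center", width_bp = 6e4,
                                      bin_bp = 1000))
  expect_gt(nrow(prof$peaks), 0)
  main <- prof$peaks[which.max(prof$peaks$height), ]
  expect_lte(abs(main$offset_bp - 10000), 1500)
})

test_that("a uniform TE field produces (almost) no peaks at a strict threshold", {
  n_peaks <- vapply(1:10, function(seed) {
    sim <- quick_sim(100 + seed, n_genes = 5, n_pseudogenes = 0, bg = 0.3,
                     contig = 8e5, focal_enrichment_factor = 1)
    prof <- density_profile(sim$genes, sim$tes, sim$seqinfo,
                            window_spec("fixed_center"), peak_z = 3)
    nrow(prof$peaks)
  }, numeric(1))
  expect_lte(sum(n_peaks), 5)
})

test_that("family representation counts midpoints per universe", {
  tes <- GRanges("c1", IRanges(c(100, 300, 1100, 5000), width = 100))
  mcols(tes)$family <- c("A", "B", "A", "A")
  focal <- GRanges("c1", IRanges(1, 1000))
  fr <- family_representation(focal, tes)
  expect_equal(fr$table$focal_count, c(1, 1))
  expect_equal(fr$table$genome_count, c(3, 1))
  expect_equal(fr$table$focal_frequency, c(0.5, 0.5))
  expect_equal(fr$table$genome_frequency, c(0.75, 0.25))
  expect_equal(sum(fr$table$focal_frequency), 1)
  expect_equal(sum(fr$table$genome_frequency), 1)
  expect_false(fr$empty_focal)
  # single family: both frequency columns are exactly 1
  one <- tes[tes$family == "A"]
  fr1 <- family_representation(focal, one)
  expect_equal(fr1$table$focal_frequency, 1)
  expect_equal(fr1$table$genome_frequency, 1)
  # focal windows devoid of TE midpoints are flagged, frequencies zero
  far <- GRanges("c1", IRanges(2e4, 3e4))
  fr0 <- family_representation(far, tes)
  expect_true(fr0$empty_focal)
  expect_equal(fr0$table$focal_frequency, c(0, 0))
  expect_error(family_representation(focal, GRanges()), "empty")
})

test_that("unbiased focal windows reproduce the genome family mixture", {
  cfg <- sim_config(seed = 86, contig_lengths = c(c1 = 3e6), n_genes = 10,
                    n_pseudogenes = 0, cluster_size = 2,
                    cluster_margin_bp = 6e4, background_te_density = 0.4,
                    focal_enrichment_factor = 1,
                    te_family_mix = c(A = 0.5, B = 0.3, C = 0.2),
                    divergence = 0, emit_sequence = FALSE)
  sim <- simulate_genome(cfg)
  focal <- expand_to_window(sim$genes, window_spec("gene_span_pad"),
                            sim$seqinfo)
  fr <- family_representation(focal, sim$tes)
  expect_lt(max(abs(fr$table$focal_frequency - fr$table$genome_frequency)),
            0.05)
})

test_that("the 1.5x regime is recovered by the permutation machinery", {
  res <- vapply(91:95, function(seed) {
    cfg <- sim_config(seed = seed,
                      contig_lengths = setNames(rep(2.5e6, 4),
                                                paste0("c", 1:4)),
                      n_genes = 20, n_pseudogenes = 0, cluster_size = 5,
                      cluster_margin_bp = 6e4, background_te_density = 0.43,
                      focal_enrichment_factor = 1.5, divergence = 0,
                      emit_sequence = FALSE)
    sim <- simulate_genome(cfg)
    focal <- expand_to_window(sim$genes, window_spec("gene_span_pad"),
                              sim$seqinfo)
    enr <- permutation_test(focal, sim$tes, sim$seqinfo, n_perm = 100,
                            seed = seed + 1)
    c(enr$fold, enr$empirical_p)
  }, numeric(2))
  expect_true(all(res[1, ] > 1.3 & res[1, ] < 1.7))
  expect_true(all(res[2, ] < 0.05))
})
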