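ref <- reference_gene()

# a random background contig with given planted strings at given positions
plant_contig <- function(len, plants, seed) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s <- paste(chars, collapse = "")
  for (p in plants) {
    stopifnot(p$pos + nchar(p$seq) - 1 <= len)
    substr(s, p$pos, p$pos + nchar(p$seq) - 1) <- p$seq
  }
  s
}

mutate_seq <- function(s, rate, seed) {
  set.seed(seed)
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

test_that("an exact exon copy is found at its coordinates with identity 1", {
  ex2 <- ref$exon_seqs[2]
  ctg <- plant_contig(20000, list(list(pos = 7001, seq = ex2)), seed = 51)
  for (m in c("seed", "exhaustive")) {
    h <- scan_exon_homology(ctg, ref$exon_seqs, method = m)
    h2 <- h[h$ref_exon_index == 2]
    expect_equal(length(h2), 1, label = m)
    expect_equal(start(h2), 7001)
    expect_equal(end(h2), 7000 + nchar(ex2))
    expect_equal(h2$percent_identity, 1.0)
    expect_equal(as.character(strand(h2)), "+")
  }
})

test_that("heavily mutated copies fall below the identity threshold", {
  ex2 <- mutate_seq(ref$exon_seqs[2], 0.25, seed = 52)
  ctg <- plant_contig(20000, list(list(pos = 7001, seq = ex2)), seed = 53)
  h <- scan_exon_homology(ctg, ref$exon_seqs, min_identity = 0.80)
  expect_length(h[h$ref_exon_index == 2], 0)
})

test_that("seeded and exhaustive scans agree on a two-copy fixture", {
  ex3 <- ref$exon_seqs[3]
  c1 <- mutate_seq(ex3, 0.05, seed = 54)
  c2 <- mutate_seq(ex3, 0.10, seed = 55)
  ctg <- plant_contig(30000, list(list(pos = 4001, seq = c1),
                                  list(pos = 21001, seq = c2)), seed = 56)
  hs <- scan_exon_homology(ctg, ref$exon_seqs, method = "seed")
  he <- scan_exon_homology(ctg, ref$exon_seqs, method = "exhaustive")
  hs3 <- hs[hs$ref_exon_index == 3]; he3 <- he[he$ref_exon_index == 3]
  expect_equal(start(hs3), start(he3))
  expect_equal(end(hs3), end(he3))
  expect_equal(hs3$percent_identity, he3$percent_identity)
  expect_equal(length(hs3), 2)
})

test_that("reverse-complementing the contig reflects hit coordinates exactly", {
  ex4 <- mutate_seq(ref$exon_seqs[4], 0.05, seed = 57)
  ctg <- plant_contig(15000, list(list(pos = 6001, seq = ex4)), seed = 58)
  h <- scan_exon_homology(ctg, ref$exon_seqs)
  rc <- as.character(reverseComplement(DNAString(ctg)))
  hrc <- scan_exon_homology(rc, ref$exon_seqs)
  h4 <- h[h$ref_exon_index == 4]; hrc4 <- hrc[hrc$ref_exon_index == 4]
  L <- nchar(ctg)
  expect_equal(start(hrc4), L - end(h4) + 1)
  expect_equal(end(hrc4), L - start(h4) + 1)
  expect_true(as.character(strand(h4)) != as.character(strand(hrc4)))
  expect_equal(h4$percent_identity, hrc4$percent_identity)
})

test_that("locus chaining needs consecutive exon indices on one strand", {
  mk <- function(idx, starts) {
    gr <- GRanges("c1", IRanges(starts, width = 150), strand = "+")
    mcols(gr)$ref_exon_index <- idx
    mcols(gr)$percent_identity <- 0.95
    mcols(gr)$aligned_columns <- 150L
    mcols(gr)$indel_bp <- 0L
    mcols(gr)$score <- 100
    gr
  }
  expect_length(select_candidate_loci(mk(c(1, 2), c(1000, 3000))), 1)
  expect_length(select_candidate_loci(mk(c(1, 3), c(1000, 3000))), 0)
  # a gap beyond max_gap_bp splits the chain
  expect_length(select_candidate_loci(mk(c(1, 2), c(1000, 30000))), 0)
})

test_that("integrity rules classify constructed lesions correctly", {
  # intact copy at zero divergence
  sim <- quick_sim(61, n_genes = 1, n_pseudogenes = 0)
  ann <- annotate_genome(sim$genome, ref)
  expect_equal(ann$summary$classification, "gene")
  expect_equal(ann$summary$reasons, "")
  call <- ann$calls[[1]]
  expect_identical(call$translation, paste0(ref$protein, "*"))

  # planted 1 bp deletion in exon 3
  cfg <- sim_config(seed = 62, contig_lengths = c(c1 = 3e5), n_genes = 0,
                    n_pseudogenes = 1,
                    lesion_spec = list(lesion("frameshift_indel", 3, 1,
                                              op = "del")),
                    cluster_size = 1, cluster_margin_bp = 6e4,
                    background_te_density = 0)
  sim <- simulate_genome(cfg)
  ann <- annotate_genome(sim$genome, ref)
  expect_equal(ann$summary$classification, "pseudogene")
  expect_match(ann$summary$reasons, "frameshift_indel")
  # the frameshift corrupts the conceptual translation downstream
  expect_match(ann$summary$reasons, "premature_stop|no_terminal_stop")

  # planted TAA at codon 50 (falls in exon 1: codons 1..57)
  cfg <- sim_config(seed = 63, contig_lengths = c(c1 = 3e5), n_genes = 0,
                    n_pseudogenes = 1,
                    lesion_spec = list(lesion("nonsense_substitution", 1,
                                              codon = 50)),
                    cluster_size = 1, cluster_margin_bp = 6e4,
                    background_te_density = 0)
  sim <- simulate_genome(cfg)
  ann <- annotate_genome(sim$genome, ref)
  expect_equal(ann$summary$classification, "pseudogene")
  expect_match(ann$summary$reasons, "premature_stop")
  call <- ann$calls[[1]]
  expect_equal(regexpr("*", call$translation, fixed = TRUE)[[1]], 50)

  # a whole-exon deletion is reported as missing_exon
  cfg <- sim_config(seed = 64, contig_lengths = c(c1 = 3e5), n_genes = 0,
                    n_pseudogenes = 1,
                    lesion_spec = list(lesion("exon_deletion", 4)),
                    cluster_size = 1, cluster_margin_bp = 6e4,
                    background_te_density = 0)
  sim <- simulate_genome(cfg)
  ann <- annotate_genome(sim$genome, ref)
  expect_equal(ann$summary$classification, "pseudogene")
  expect_match(ann$summary$reasons, "missing_exon")
  expect_equal(ann$summary$n_exons_hit, 5)
})

test_that("in-frame indels alone do not pseudogenize", {
  sim <- quick_sim(65, n_genes = 1, n_pseudogenes = 0)
  g <- sim$genes[1]
  ex3 <- sim$genes$exons[[1]]
  ex3 <- ex3[ex3$exon_rank == 3]
  # excise 3 bp from the middle of exon 3 (in-frame deletion)
  s <- as.character(sim$genome[[1]])
  cut_at <- start(ex3) + 90
  s2 <- paste0(substr(s, 1, cut_at - 1), substr(s, cut_at + 3, nchar(s)))
  ann <- annotate_genome(DNAStringSet(c(c1 = s2)), ref)
  expect_equal(ann$summary$classification, "gene")
  expect_equal(ann$summary$reasons, "")
  expect_equal(ann$calls[[1]]$indel_by_exon[3], 3)
})

test_that("planted labels and lesion reasons are recovered at 5% divergence", {
  cfg <- sim_config(seed = 66, contig_lengths = c(c1 = 8e5, c2 = 8e5),
                    n_genes = 10, n_pseudogenes = 10, cluster_size = 10,
                    cluster_margin_bp = 6e4, background_te_density = 0,
                    divergence = 0.05)
  sim <- simulate_genome(cfg)
  ann <- annotate_genome(sim$genome, ref)
  m <- merge(sim$truth, ann$summary, by = "start")
  expect_equal(nrow(m), 20)
  expect_identical(m$classification, m$label)
  pseudo <- m[m$label == "pseudogene", ]
  ok <- mapply(function(les, rs) grepl(lesion_reason[[les]], rs),
               pseudo$lesions, pseudo$reasons)
  expect_true(all(ok))
})
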