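motifs <- built_in_motifs()

test_that("DDxxD scanning matches positional examples", {
  h <- scan_motif("AAADDYLDAAA", motifs$FARM)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 4) # 1-based
  expect_equal(h$match, "DDYLD")
  expect_equal(nrow(scan_motif("DELID", motifs$FARM)), 0)
  # X matches only wildcard columns
  expect_equal(nrow(scan_motif("DDXXD", motifs$FARM)), 1)
  expect_equal(nrow(scan_motif("XDYLD", motifs$FARM)), 0)
})

test_that("scan_motif equals the brute-force membership oracle", {
  set.seed(71)
  defs <- list(motifs$FARM, motifs$IGM3, motifs$IGM6,
               motif_definition("mixed", "K[TS]x[ILV]E"))
  for (rep in 1:25) {
    p <- paste(sample(tefam:::AA20, 1000, replace = TRUE), collapse = "")
    for (m in defs) {
      expect_identical(scan_motif(p, m)$start,
                       oracle_motif_hits(p, m$columns))
    }
  }
})

test_that("FARM/SARM assignment uses first hit plus downstream-separation rule", {
  lk <- strrep("A", 100)
  p <- paste0("MXX", "DDYLD", strrep("G", 84), "DDIMD", lk)
  fs <- assign_farm_sarm(p)
  expect_equal(fs$farm_start, 4)
  expect_equal(fs$sarm_start, 4 + 5 + 84)
  # a second hit closer than 80 residues is not accepted as SARM
  p2 <- paste0("MXX", "DDYLD", strrep("G", 20), "DDIMD", lk)
  fs2 <- assign_farm_sarm(p2)
  expect_equal(fs2$farm_start, 4)
  expect_true(is.na(fs2$sarm_start))
})

test_that("family calls follow the canonical / divergent / indeterminate rules", {
  panel <- simulate_protein_panel(n_per_class = 6, seed = 72)
  calls <- classify_proteins(panel$proteins)
  expect_identical(calls$call, panel$truth$class)
  # order independence: permuting the motif set never changes a call
  p <- panel$proteins[[1]]
  shuffled <- motifs[sample(names(motifs))]
  expect_identical(classify_ids_family(p, motifs)$call,
                   classify_ids_family(p, shuffled)$call)
  # a protein lacking FARM is indeterminate even with everything else
  noFarm <- panel$proteins[panel$truth$class == "indeterminate"][[1]]
  expect_identical(classify_ids_family(noFarm)$call, "indeterminate")
})

test_that("FARM/SARM detection degrades monotonically with noise", {
  rates <- vapply(c(0, 0.05, 0.1, 0.2), function(noise) {
    panel <- simulate_protein_panel(n_per_class = 30, noise = noise,
                                    seed = 73)
    canon <- panel$proteins[panel$truth$class == "canonical"]
    mean(vapply(canon, function(p) {
      fs <- assign_farm_sarm(p)
      !is.na(fs$farm_start) && !is.na(fs$sarm_start)
    }, logical(1)))
  }, numeric(1))
  expect_equal(rates[1], 1.0)
  expect_true(all(diff(rates) <= 0))
})

test_that("phylogeny filtering keeps >= 150 aa sequences with both motifs", {
  core <- paste0("DDYLD", strrep("G", 84), "DDIMD") # 94 aa, both motifs
  seqs <- c(short_both = paste0(core, strrep("A", 149 - 94)),        # 149 aa
            long_both = paste0(core, strrep("A", 150 - 94)),         # 150 aa
            long_farm_only = paste0("DDYLD", strrep("A", 195)),
            long_none = strrep("A", 200))
  kept <- filter_phylogeny_set(seqs)
  expect_identical(names(kept), "long_both")
})

test_that("trained DDxxD regex reproduces the built-in scanner", {
  # every residue appears in each wildcard column so the trained definition
  # saturates the wildcard rule
  inst <- paste0("DD", tefam:::AA20, rev(tefam:::AA20), "D")
  trained <- build_motif_regex(inst, 1:5, name = "FARM")
  set.seed(74)
  for (rep in 1:20) {
    p <- paste(sample(c(tefam:::AA20, "D", "D"), 300, replace = TRUE),
               collapse = "")
    expect_identical(scan_motif(p, trained)$start,
                     scan_motif(p, motifs$FARM)$start)
  }
})

test_that("regex training applies thresholds and rejects gappy columns", {
  aln <- c(rep("MDKLV", 10))
  m <- build_motif_regex(aln, 1:5)
  expect_identical(vapply(m$columns, paste, character(1), collapse = ""),
                   c("M", "D", "K", "L", "V"))
  # 96/4 split at threshold 0.05 keeps only the major residue
  aln2 <- vapply(c(rep("D", 24), "E"), function(ch)
    paste0("A", ch, "A"), character(1))
  m2 <- build_motif_regex(aln2, 1:3, name = "x", min_residue_freq = 0.05)
  expect_identical(m2$columns[[2]], "D")
  # gap-majority column inside the motif is an error naming the column
  aln3 <- c(rep("A-C", 7), rep("AAC", 3))
  expect_error(build_motif_regex(aln3, 1:3), "column 2")
  expect_error(build_motif_regex(aln[1:3], 1:5), "at least 5")
  # self-consistency: training sequences match their own trained motif
  set.seed(75)
  train <- vapply(1:12, function(i)
    paste(sample(c("K", "R"), 6, replace = TRUE), collapse = ""),
    character(1))
  m3 <- build_motif_regex(train, 1:6, min_residue_freq = 0.01)
  for (s in train) expect_true(1 %in% scan_motif(s, m3)$start)
})

test_that("logo matrices give textbook frequencies and information content", {
  lm <- logo_matrix(rep("DDYLD", 8))
  expect_equal(colSums(lm$freq), rep(1, 5))
  expect_equal(lm$ic, rep(log2(20), 5), tolerance = 1e-12)
  # a uniform 20-residue column has zero information
  lm2 <- logo_matrix(tefam:::AA20)
  expect_equal(lm2$ic, 0, tolerance = 1e-12)
  # random columns match an independent entropy computation
  set.seed(76)
  inst <- vapply(1:40, function(i)
    paste(sample(tefam:::AA20, 4, replace = TRUE), collapse = ""),
    character(1))
  lm3 <- logo_matrix(inst)
  mat <- do.call(rbind, strsplit(inst, ""))
  for (j in 1:4) {
    f <- table(factor(mat[, j], levels = tefam:::AA20)) / nrow(mat)
    ent <- -sum(f[f > 0] * log2(f[f > 0]))
    expect_equal(lm3$ic[j], log2(20) - ent, tolerance = 1e-12)
  }
  expect_error(logo_matrix(c("DDY", "DDYL")), "unequal")
})

test_that("motif definitions survive a JSON round-trip", {
  f <- tempfile(fileext = ".json")
  write_motifs_json(motifs, f)
  back <- read_motifs_json(f)
  expect_identical(names(back), names(motifs))
  for (nm in names(motifs)) {
    expect_identical(back[[nm]]$columns, motifs[[nm]]$columns)
  }
})
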