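## Permutation-based TE co-localization statistics: focal-vs-null density,
## strand-oriented meta-locus profiles with satellite-peak detection, and
## TE-family composition.

#' Mean TE density of a window set
#'
#' Unweighted mean of per-window TE density. The default (and the
#' definition used throughout the package) is the merged base-pair coverage
#' fraction ([coverage_fraction()]); `stat = "count"` instead measures
#' elements per kb (midpoint containment), exposed for sensitivity analyses.
#'
#' @param windows A non-empty `GRanges` of windows.
#' @param tes TE annotations (`GRanges` or [te_coverage()] `RleList`;
#'   `"count"` mode requires a `GRanges`).
#' @param stat `"coverage"` (default) or `"count"`.
#' @return A single number: mean coverage fraction, or mean elements per kb.
#' @export
mean_density <- function(windows, tes, stat = c("coverage", "count")) {
  stat <- match.arg(stat)
  if (length(windows) == 0L) stop("empty window set")
  if (stat == "coverage") {
    return(mean(coverage_fraction(windows, tes)))
  }
  if (!is(tes, "GRanges")) stop("stat = 'count' needs TE annotations as GRanges")
  mid <- floor((start(tes) + end(tes)) / 2)
  midgr <- GRanges(seqnames(tes), IRanges(mid, mid))
  n <- countOverlaps(windows, midgr, ignore.strand = TRUE)
  mean(1000 * n / width(windows))
}

#' Permutation test of TE enrichment around focal loci
#'
#' Compares the mean TE density of the focal windows against a null built by
#' resampling: each permutation draws as many random fixed-width windows as
#' there are focal windows ([sample_random_windows()]) and records their mean
#' density. The empirical p-value is plus-one corrected,
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, so it is never exactly zero;
#' `fold` is `observed / mean(null)` and `percent_of_null` is `fold * 100`
#' (e.g. 150 means the focal density is 150% of the permutation average).
#' One-sided (enrichment) by default; `alternative = "two.sided"` doubles the
#' smaller tail.
#'
#' @param focal_windows A non-empty `GRanges` of focal windows (typically
#'   [expand_to_window()] output).
#' @param tes TE annotations (`GRanges` or [te_coverage()] `RleList`).
#' @param contigs Contig lengths (see [expand_to_window()]).
#' @param n_perm Number of permutations (default 1000).
#' @param width Null window width in bp (default 100000).
#' @param seed Optional integer seed for the resampling.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param stat `"coverage"` (default) or `"count"`; see [mean_density()].
#' @param exclude Optional mask passed to [sample_random_windows()].
#' @return A `te_enrichment` list: `observed_mean`, `null_means`, `fold`,
#'   `percent_of_null`, `empirical_p`, `n_perm`, `seed`,
#'   `per_window_densities`, `window_widths`, `alternative`.
#' @export
permutation_test <- function(focal_windows, tes, contigs, n_perm = 1000L,
                             width = 100000L, seed = NULL,
                             alternative = c("greater", "two.sided"),
                             stat = c("coverage", "count"),
                             exclude = NULL) {
  alternative <- match.arg(alternative)
  stat <- match.arg(stat)
  if (length(focal_windows) == 0L) stop("no focal windows supplied")
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L)
  si <- as_contigs(contigs)
  if (stat == "coverage") {
    dens_fun <- local({
      cvg <- if (is(tes, "RleList")) tes else te_coverage(tes, si)
      function(w) coverage_fraction(w, cvg)
    })
  } else {
    if (!is(tes, "GRanges")) stop("stat = 'count' needs TE GRanges")
    dens_fun <- local({
      mid <- floor((start(tes) + end(tes)) / 2)
      midgr <- GRanges(seqnames(tes), IRanges(mid, mid))
      function(w) 1000 * countOverlaps(w, midgr, ignore.strand = TRUE) /
        width(w)
    })
  }
  per_win <- dens_fun(focal_windows)
  observed <- mean(per_win)
  k <- length(focal_windows)
  null_means <- with_seed(seed, {
    all_wins <- sample_random_windows(si, width, n_perm * k,
                                      exclude = exclude)
    v <- dens_fun(all_wins)
    colMeans(matrix(v, nrow = k, ncol = n_perm))
  })
  p_hi <- (1 + sum(null_means >= observed)) / (n_perm + 1)
  p <- if (alternative == "greater") {
    p_hi
  } else {
    p_lo <- (1 + sum(null_means <= observed)) / (n_perm + 1)
    min(1, 2 * min(p_hi, p_lo))
  }
  structure(list(observed_mean = observed, null_means = null_means,
                 fold = observed / mean(null_means),
                 percent_of_null = 100 * observed / mean(null_means),
                 empirical_p = p, n_perm = n_perm, seed = seed,
                 per_window_densities = per_win,
                 window_widths = width(focal_windows),
                 alternative = alternative),
            class = "te_enrichment")
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat(sprintf(paste0(
    "TE enrichment: observed mean density %.4f vs null %.4f ",
    "(%.0f%% of null, fold %.3f)\n  empirical p = %.4g (%s, %d permutations)\n"),
    x$observed_mean, mean(x$null_means), x$percent_of_null, x$fold,
    x$empirical_p, x$alternative, x$n_perm))
  invisible(x)
}

#' Meta-locus TE density profile with satellite-peak detection
#'
#' Builds a fixed-width window centred on each focal gene's midpoint, splits
#' it into strand-oriented bins (bin index increases 5' to 3' along the
#' gene), and averages the per-bin coverage fractions over loci. Peaks are
#' local maxima of the moving-average-smoothed profile exceeding
#' `mean + peak_z * sd` of the smoothed profile; their offsets are signed bp
#' from the gene center (negative = upstream in gene orientation). Secondary
#' ("satellite") peaks at the paralog spacing reveal regularly spaced
#' neighbouring family members.
#'
#' Genes whose centred window would run off the contig are dropped with a
#' message (the profile needs equal-width windows).
#'
#' @param genes A non-empty stranded `GRanges` of focal genes.
#' @param tes TE annotations (`GRanges` or [te_coverage()] `RleList`).
#' @param contigs Contig lengths.
#' @param spec A [window_spec()]; `width_bp` and `bin_bp` are used.
#' @param smoothing_bins Moving-average window (odd; default 3).
#' @param peak_z Peak threshold in profile standard deviations (default 2).
#' @return A `te_profile` list: `bin_offsets` (bp from gene center, 5'->3'),
#'   `mean_density`, `n_loci`, `peaks` (data.frame of `offset_bp`, `height`,
#'   `prominence`), `smoothed`.
#' @export
density_profile <- function(genes, tes, contigs,
                            spec = window_spec("fixed_center"),
                            smoothing_bins = 3L, peak_z = 2.0) {
  if (length(genes) == 0L) stop("no focal genes supplied")
  si <- as_contigs(contigs)
  nb <- spec$width_bp %/% spec$bin_bp
  if (nb < smoothing_bins) stop("fewer bins than the smoothing window")
  cspec <- window_spec("fixed_center", width_bp = spec$width_bp,
                       bin_bp = spec$bin_bp, pad_bp = spec$pad_bp)
  wins <- expand_to_window(genes, cspec, si)
  keep <- !wins$clipped
  if (!all(keep)) {
    message(sum(!keep), " gene(s) dropped: centred window clipped at contig edge")
  }
  wins <- wins[keep]
  genes <- genes[keep]
  if (length(wins) == 0L) stop("no unclipped focal windows remain")
  cvg <- if (is(tes, "RleList")) tes else te_coverage(tes, si)
  strands <- as.character(strand(genes))
  strands[!strands %in% c("+", "-")] <- "+"
  m <- binned_coverage_matrix(wins, strands, cvg, spec$bin_bp)
  prof <- colMeans(m)
  offsets <- (seq_len(nb) - 1L) * spec$bin_bp + spec$bin_bp / 2 -
    spec$width_bp / 2
  sm <- as.numeric(stats::filter(prof, rep(1 / smoothing_bins, smoothing_bins),
                                 sides = 2))
  peaks <- find_profile_peaks(sm, offsets, peak_z)
  structure(list(bin_offsets = offsets, mean_density = prof,
                 n_loci = length(wins), peaks = peaks, smoothed = sm,
                 bin_bp = spec$bin_bp),
            class = "te_profile")
}

# Local maxima of the smoothed profile above mean + z * sd; prominence is
# height minus the profile mean.
find_profile_peaks <- function(sm, offsets, peak_z) {
  ok <- !is.na(sm)
  mu <- mean(sm[ok]); sdv <- sd(sm[ok])
  thr <- mu + peak_z * sdv
  n <- length(sm)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    if (!ok[i] || sm[i] < thr) next
    left <- if (i > 1 && ok[i - 1]) sm[i - 1] else -Inf
    right <- if (i < n && ok[i + 1]) sm[i + 1] else -Inf
    if (sm[i] >= left && sm[i] > right) is_peak[i] <- TRUE
    if (sm[i] >= left && i == n) is_peak[i] <- TRUE
  }
  idx <- which(is_peak)
  data.frame(offset_bp = offsets[idx], height = sm[idx],
             prominence = sm[idx] - mu)
}

#' @export
print.te_profile <- function(x, ...) {
  cat("TE meta-locus profile over", x$n_loci, "loci,",
      length(x$bin_offsets), "bins of", x$bin_bp, "bp\n")
  if (nrow(x$peaks)) {
    cat("peaks at (bp from center):",
        paste(round(x$peaks$offset_bp), collapse = ", "), "\n")
  } else {
    cat("no peaks above threshold\n")
  }
  invisible(x)
}

#' TE family composition: focal windows vs whole genome
#'
#' Counts TE elements (not base pairs) whose midpoint falls inside any focal
#' window, versus all elements genome-wide, and reports per-family relative
#' frequencies in each universe. When no element midpoint falls in a focal
#' window, focal frequencies are reported as 0 and `empty_focal` is set.
#'
#' @param focal_windows A `GRanges` of focal windows.
#' @param tes A non-empty `GRanges` with a `family` metadata column.
#' @return A `te_family_rep` list: `table` (data.frame of `family`,
#'   `focal_count`, `genome_count`, `focal_frequency`, `genome_frequency`)
#'   and `empty_focal`.
#' @export
family_representation <- function(focal_windows, tes) {
  if (length(tes) == 0L) stop("empty TE set")
  if (is.null(tes$family)) stop("TE annotations lack a 'family' column")
  mid <- floor((start(tes) + end(tes)) / 2)
  midgr <- GRanges(seqnames(tes), IRanges(mid, mid))
  in_focal <- overlapsAny(midgr, focal_windows, ignore.strand = TRUE)
  fams <- sort(unique(tes$family))
  gcount <- table(factor(tes$family, levels = fams))
  fcount <- table(factor(tes$family[in_focal], levels = fams))
  nf <- sum(fcount)
  tab <- data.frame(family = fams,
                    focal_count = as.integer(fcount),
                    genome_count = as.integer(gcount),
                    focal_frequency = if (nf > 0) as.numeric(fcount) / nf
                                      else rep(0, length(fams)),
                    genome_frequency = as.numeric(gcount) / sum(gcount))
  structure(list(table = tab, empty_focal = nf == 0L),
            class = "te_family_rep")
}

#' @export
print.te_family_rep <- function(x, ...) {
  cat("TE family representation (focal vs genome):\n")
  print(x$table, row.names = FALSE, digits = 3)
  if (x$empty_focal) cat("note: no TE midpoint inside focal windows\n")
  invisible(x)
}

#' Write an enrichment result as TSV + JSON
#' @param enr A [permutation_test()] result.
#' @param prefix Output path prefix (writes `<prefix>.tsv`, `<prefix>.json`).
#' @return The JSON path, invisibly.
#' @export
write_enrichment <- function(enr, prefix) {
  df <- data.frame(statistic = c("observed_mean", "null_mean", "fold",
                                 "percent_of_null", "empirical_p", "n_perm"),
                   value = c(enr$observed_mean, mean(enr$null_means),
                             enr$fold, enr$percent_of_null, enr$empirical_p,
                             enr$n_perm))
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(observed_mean = enr$observed_mean,
         null_mean = mean(enr$null_means), fold = enr$fold,
         percent_of_null = enr$percent_of_null,
         empirical_p = enr$empirical_p, n_perm = enr$n_perm,
         seed = enr$seed, alternative = enr$alternative,
         per_window_densities = enr$per_window_densities,
         window_widths = enr$window_widths),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}
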