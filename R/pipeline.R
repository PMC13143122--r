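## Orchestration: annotate -> enrich -> classify on simulated or supplied
## data, with a stable JSON-able report; plus the enantiomer-ratio statistic
## used for chiral product profiling of enzyme variants.

#' Run the full analysis pipeline
#'
#' Executes the three analysis stages on either a simulated genome (pass a
#' [sim_config()]) or supplied data (genome + TE annotations, optionally
#' proteins): locus discovery and integrity classification
#' ([annotate_genome()]), TE co-localization statistics around the called
#' loci ([permutation_test()], [density_profile()],
#' [family_representation()]), and motif classification of the called loci's
#' conceptual translations plus any supplied proteins
#' ([classify_proteins()]).
#'
#' The returned report has a stable schema: every run emits the same keys,
#' with explicit `NULL`s for analyses that could not run (e.g. enrichment
#' without TE annotations). Re-running with the same inputs and seed gives a
#' byte-identical JSON report.
#'
#' @param config A [sim_config()] to simulate inputs, or `NULL` when
#'   supplying real data.
#' @param genome A named `DNAStringSet` or FASTA path (ignored when `config`
#'   is given).
#' @param tes TE annotations `GRanges` or BED/GFF3 path.
#' @param proteins Optional `AAStringSet` or FASTA path to classify in
#'   addition to the called loci translations.
#' @param ref Reference gene model for the homology scan.
#' @param spec [window_spec()] for focal windows and profiles.
#' @param n_perm,null_width Permutation count and null window width.
#' @param min_identity,min_consecutive,max_gap_bp,scan_method Locus discovery
#'   parameters (see [annotate_genome()]).
#' @param motifs Motif set for protein classification.
#' @param smoothing_bins,peak_z Profile peak detection parameters.
#' @param seed Integer seed driving the permutation resampling (and the
#'   simulation, when `config` carries no seed of its own).
#' @param output_dir Optional directory; when given, per-stage TSV/GFF3/JSON
#'   artifacts and the `report.json` are written there.
#' @return A `pipeline_report` list; see Details for keys.
#' @export
run_pipeline <- function(config = NULL, genome = NULL, tes = NULL,
                         proteins = NULL, ref = reference_gene(),
                         spec = window_spec(), n_perm = 1000L,
                         null_width = 100000L, min_identity = 0.80,
                         min_consecutive = 2L, max_gap_bp = 20000L,
                         scan_method = "seed", motifs = built_in_motifs(),
                         smoothing_bins = 3L, peak_z = 2.0,
                         seed = 1L, output_dir = NULL) {
  if (!is.null(config) && (!is.null(genome) || !is.null(tes))) {
    stop("supply either a sim_config or real inputs, not both")
  }
  sim <- NULL
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    sim <- simulate_genome(config)
    genome <- sim$genome
    tes <- sim$tes
    if (is.null(genome)) {
      stop("run_pipeline needs sequence: use emit_sequence = TRUE")
    }
  } else {
    if (is.null(genome)) stop("no genome supplied")
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (is.character(tes)) tes <- read_te_annotations(tes)
    if (is.character(proteins)) proteins <- readAAStringSet(proteins)
  }
  si <- Seqinfo(names(genome), width(genome))

  ann <- annotate_genome(genome, ref, min_identity, min_consecutive,
                         max_gap_bp, method = scan_method)

  enrichment <- NULL; profile <- NULL; famrep <- NULL
  if (!is.null(tes) && length(tes) && length(ann$loci)) {
    loci <- ann$loci
    seqlevels(loci) <- seqlevels(si)
    seqinfo(loci) <- si
    focal <- expand_to_window(loci, window_spec("gene_span_pad",
                                                pad_bp = spec$pad_bp), si)
    cvg <- te_coverage(tes, si)
    enrichment <- permutation_test(focal, cvg, si, n_perm = n_perm,
                                   width = null_width,
                                   seed = child_seed(seed, 2))
    profile <- tryCatch(
      density_profile(loci, cvg, si,
                      window_spec("fixed_center", width_bp = spec$width_bp,
                                  bin_bp = spec$bin_bp),
                      smoothing_bins, peak_z),
      error = function(e) NULL)
    famrep <- family_representation(focal, tes)
  }

  prot_set <- AAStringSet()
  if (length(ann$calls)) {
    tr <- vapply(ann$calls, `[[`, character(1), "translation")
    names(tr) <- ann$summary$locus_id
    prot_set <- AAStringSet(tr[nchar(tr) > 0])
  }
  if (!is.null(proteins)) prot_set <- c(prot_set, AAStringSet(proteins))
  motif_calls <- if (length(prot_set)) {
    classify_proteins(prot_set, motifs)
  } else NULL

  report <- structure(list(
    version = as.character(utils::packageVersion("tefam")),
    seed = seed,
    params = list(n_perm = n_perm, null_width = null_width,
                  min_identity = min_identity,
                  min_consecutive = min_consecutive,
                  max_gap_bp = max_gap_bp, pad_bp = spec$pad_bp,
                  width_bp = spec$width_bp, bin_bp = spec$bin_bp,
                  scan_method = scan_method),
    n_contigs = length(genome),
    genome_bp = sum(as.double(width(genome))),
    loci = ann$summary,
    n_loci = nrow(ann$summary),
    n_genes = sum(ann$summary$classification == "gene"),
    n_pseudogenes = sum(ann$summary$classification == "pseudogene"),
    enrichment = if (is.null(enrichment)) NULL else list(
      observed_mean = enrichment$observed_mean,
      null_mean = mean(enrichment$null_means),
      fold = enrichment$fold,
      percent_of_null = enrichment$percent_of_null,
      empirical_p = enrichment$empirical_p,
      n_perm = enrichment$n_perm),
    profile = if (is.null(profile)) NULL else list(
      n_loci = profile$n_loci,
      peak_offsets_bp = profile$peaks$offset_bp,
      peak_heights = profile$peaks$height),
    family_representation = if (is.null(famrep)) NULL else famrep$table,
    motif_calls = motif_calls,
    annotation = ann,
    sim_truth = if (is.null(sim)) NULL else sim$truth
  ), class = "pipeline_report")

  if (!is.null(output_dir)) write_report(report, output_dir, profile = profile)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("tefam pipeline report (v", x$version, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  loci:", x$n_loci, "(", x$n_genes, "genes /", x$n_pseudogenes,
      "pseudogenes )\n")
  if (!is.null(x$enrichment)) {
    cat(sprintf("  TE enrichment: %.3f vs %.3f (%.0f%% of null), p = %.4g\n",
                x$enrichment$observed_mean, x$enrichment$null_mean,
                x$enrichment$percent_of_null, x$enrichment$empirical_p))
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Emits `report.json` plus per-stage artifacts (`loci.gff3`, `loci.tsv`,
#' `enrichment.tsv/json`, `profile.tsv`, `te_families.tsv`,
#' `motif_calls.tsv`) under `dir`. Every TSV carries a header line with the
#' package version and seed.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @param profile Optional `te_profile` for the full binned profile TSV.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, profile = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# tefam %s seed=%s", report$version, report$seed)
  put <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
  }
  if (!is.null(report$loci) && nrow(report$loci)) {
    put(report$loci, "loci.tsv")
    rtracklayer::export(local({
      gr <- report$annotation$loci
      mcols(gr)$type <- ifelse(report$loci$classification == "gene",
                               "gene", "pseudogene")
      mcols(gr)$ID <- report$loci$locus_id
      mcols(gr)$reasons <- report$loci$reasons
      gr
    }), file.path(dir, "loci.gff3"), format = "gff3")
  }
  if (!is.null(report$enrichment)) {
    df <- data.frame(statistic = names(report$enrichment),
                     value = unlist(report$enrichment))
    put(df, "enrichment.tsv")
  }
  if (!is.null(profile)) {
    put(data.frame(offset_bp = profile$bin_offsets,
                   mean_density = profile$mean_density,
                   smoothed = profile$smoothed), "profile.tsv")
  }
  if (!is.null(report$family_representation)) {
    put(report$family_representation, "te_families.tsv")
  }
  if (!is.null(report$motif_calls)) put(report$motif_calls, "motif_calls.tsv")
  json <- report
  json$annotation <- NULL # R objects; the tabular views carry the content
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(dir)
}

## --- enantiomer ratio statistic --------------------------------------------

#' Enantiomer ratio comparison between two groups
#'
#' For each replicate the ratio of the R enantiomer is its chromatographic
#' peak area divided by the summed areas of both enantiomers,
#' `area_r / (area_r + area_s)`. Group means are reported as percentages and
#' the two groups are compared with a two-tailed two-sample t test — Welch's
#' unequal-variance form by default, pooled-variance Student's t with
#' `var_equal = TRUE`.
#'
#' @param data A data.frame with columns `group`, `area_r`, `area_s` (one
#'   row per replicate; exactly two groups, each with at least 2 replicates).
#' @param var_equal Use the pooled-variance Student's t instead of Welch.
#' @return An `enantiomer_test` list: `ratios` (per-replicate data.frame),
#'   `group_means_percent`, `t`, `df`, `p_value`, `method`.
#' @examples
#' d <- data.frame(group = rep(c("wt", "mut"), each = 3),
#'                 area_r = c(65, 64, 66, 91, 90, 92),
#'                 area_s = c(35, 36, 34, 9, 10, 8))
#' enantiomer_ratio_test(d)
#' @export
enantiomer_ratio_test <- function(data, var_equal = FALSE) {
  need <- c("group", "area_r", "area_s")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "))
  }
  if (any(data$area_r < 0 | data$area_s < 0)) stop("negative peak area")
  both_zero <- data$area_r == 0 & data$area_s == 0
  if (any(both_zero)) {
    stop("replicate ", which(both_zero)[1],
         " has zero area for both enantiomers")
  }
  groups <- unique(as.character(data$group))
  if (length(groups) != 2L) stop("exactly two groups required")
  tab <- table(data$group)
  if (any(tab < 2L)) stop("each group needs at least 2 replicates")
  ratio <- data$area_r / (data$area_r + data$area_s)
  g1 <- ratio[data$group == groups[1]]
  g2 <- ratio[data$group == groups[2]]
  if (sd(g1) == 0 && sd(g2) == 0) {
    # zero within-group variance: the t statistic is 0 (equal means) or
    # infinite (different means); report honestly rather than erroring
    same <- mean(g1) == mean(g2)
    tt <- list(statistic = c(t = if (same) 0 else
                               sign(mean(g1) - mean(g2)) * Inf),
               parameter = c(df = length(g1) + length(g2) - 2),
               p.value = if (same) 1 else 0)
    method <- "degenerate (zero within-group variance)"
  } else {
    tt <- t.test(g1, g2, var.equal = var_equal)
    method <- if (var_equal) "Student (pooled)" else "Welch"
  }
  structure(list(
    ratios = data.frame(group = data$group, ratio = ratio),
    group_means_percent = setNames(
      c(100 * mean(g1), 100 * mean(g2)), groups),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = method),
    class = "enantiomer_test")
}

#' @export
print.enantiomer_test <- function(x, ...) {
  cat("enantiomer ratio test (", x$method, "):\n", sep = "")
  for (g in names(x$group_means_percent)) {
    cat(sprintf("  %s: %.1f%% R\n", g, x$group_means_percent[[g]]))
  }
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Simulate a chiral chromatography assay
#'
#' Generates replicate peak areas for two enzyme variants with specified true
#' R-enantiomer fractions, for exercising [enantiomer_ratio_test()].
#'
#' @param ratio_r Length-2 numeric: true R fraction per group.
#' @param n Replicates per group (default 3, the usual triplicate design).
#' @param total_area Mean total peak area.
#' @param cv Coefficient of variation of each peak area.
#' @param groups Group labels.
#' @param seed Optional seed.
#' @return A data.frame suitable for [enantiomer_ratio_test()].
#' @export
simulate_enantiomer_assay <- function(ratio_r = c(0.65, 0.91), n = 3L,
                                      total_area = 1000, cv = 0.05,
                                      groups = c("wild_type", "mutant"),
                                      seed = NULL) {
  stopifnot(length(ratio_r) == 2L, length(groups) == 2L)
  with_seed(seed, {
    rows <- lapply(1:2, function(g) {
      r <- pmax(0, rnorm(n, ratio_r[g] * total_area,
                         cv * ratio_r[g] * total_area))
      s <- pmax(0, rnorm(n, (1 - ratio_r[g]) * total_area,
                         cv * (1 - ratio_r[g]) * total_area))
      data.frame(group = groups[g], area_r = r, area_s = s)
    })
    do.call(rbind, rows)
  })
}
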