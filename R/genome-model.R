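#' Window construction parameters
#'
#' Bundles the conventions used to turn a gene locus into the genomic window
#' in which TE density is measured: either the gene span padded on both sides
#' (default 50 kb, the convention for focal loci) or a fixed-width window
#' centred on the gene midpoint (default 100 kb, the convention for the
#' permutation null), subdivided into bins (default 1 kb) for meta-locus
#' profiles.
#'
#' @param mode `"gene_span_pad"` (gene span extended by `pad_bp` on each side)
#'   or `"fixed_center"` (window of exactly `width_bp` centred on the gene
#'   midpoint).
#' @param pad_bp Padding in bp for `gene_span_pad` mode.
#' @param width_bp Window width in bp for `fixed_center` mode; must be a
#'   multiple of `bin_bp`.
#' @param bin_bp Bin width in bp for binned profiles.
#' @return A `window_spec` object (a validated list).
#' @examples
#' window_spec()
#' window_spec("fixed_center", width_bp = 2e4, bin_bp = 500)
#' @export
window_spec <- function(mode = c("gene_span_pad", "fixed_center"),
                        pad_bp = 50000L, width_bp = 100000L, bin_bp = 1000L) {
  mode <- match.arg(mode)
  pad_bp <- as.integer(pad_bp)
  width_bp <- as.integer(width_bp)
  bin_bp <- as.integer(bin_bp)
  stopifnot(pad_bp > 0L, width_bp > 0L, bin_bp > 0L)
  if (width_bp %% bin_bp != 0L) {
    stop("width_bp (", width_bp, ") must be divisible by bin_bp (", bin_bp, ")")
  }
  structure(list(mode = mode, pad_bp = pad_bp, width_bp = width_bp,
                 bin_bp = bin_bp),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("window_spec: mode=", x$mode, " pad=", x$pad_bp, " width=", x$width_bp,
      " bin=", x$bin_bp, "\n", sep = "")
  invisible(x)
}

# Coerce contig descriptions (Seqinfo, named lengths, or any object with a
# seqinfo) to a Seqinfo.
as_contigs <- function(contigs) {
  if (is(contigs, "Seqinfo")) return(contigs)
  if (is.numeric(contigs) && !is.null(names(contigs))) {
    return(Seqinfo(seqnames = names(contigs), seqlengths = as.integer(contigs)))
  }
  if (is(contigs, "DNAStringSet")) {
    return(Seqinfo(seqnames = names(contigs), seqlengths = width(contigs)))
  }
  si <- try(seqinfo(contigs), silent = TRUE)
  if (!inherits(si, "try-error")) return(si)
  stop("cannot interpret `contigs` as contig lengths")
}

#' Expand gene loci to measurement windows
#'
#' Turns each gene span into the window in which TE density is measured, per
#' a [window_spec()]: the span padded by `pad_bp` on each side, or a window of
#' `width_bp` centred on the span midpoint. Windows are clipped to contig
#' bounds; the `clipped` metadata column records when that happened, and
#' clipped windows keep their (shorter) realized width.
#'
#' @param genes A `GRanges` of gene spans (strand is carried through).
#' @param spec A [window_spec()].
#' @param contigs Contig lengths: a `Seqinfo`, a named numeric vector, or a
#'   `DNAStringSet` genome.
#' @return A `GRanges` parallel to `genes`, with metadata column `clipped`.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("ctg1", 1e6)
#' g <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(60001, 62000), "+")
#' expand_to_window(g, window_spec(), si)
#' @export
expand_to_window <- function(genes, spec = window_spec(), contigs) {
  stopifnot(is(genes, "GRanges"), inherits(spec, "window_spec"))
  si <- as_contigs(contigs)
  lens <- seqlengths(si)[as.character(seqnames(genes))]
  if (anyNA(lens)) {
    bad <- as.character(seqnames(genes))[is.na(lens)]
    stop("gene(s) on contig(s) absent from `contigs`: ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(end(genes) > lens)) {
    stop("gene extends beyond its contig")
  }
  if (spec$mode == "gene_span_pad") {
    s <- start(genes) - spec$pad_bp
    e <- end(genes) + spec$pad_bp
  } else {
    mid <- floor((start(genes) - 1 + end(genes)) / 2) # 0-based midpoint
    s <- mid - spec$width_bp %/% 2L + 1L
    e <- mid + spec$width_bp %/% 2L
  }
  cs <- pmax(s, 1L)
  ce <- pmin(e, lens)
  out <- GRanges(seqnames(genes), IRanges(cs, ce), strand = strand(genes),
                 seqinfo = si)
  mcols(out)$clipped <- (cs != s) | (ce != e)
  names(out) <- names(genes)
  out
}

#' Merged TE base-pair coverage as run-length vectors
#'
#' Collapses a TE annotation set to a 0/1 per-base occupancy signal (nested
#' and overlapping elements merged), one `Rle` per contig. Precomputing this
#' makes repeated window-density queries (notably the permutation null) cheap.
#'
#' @param tes A `GRanges` of TE annotations (strand and family ignored).
#' @param contigs Contig lengths (see [expand_to_window()]).
#' @return An `RleList` of 0/1 integer coverage, one element per contig.
#' @export
te_coverage <- function(tes, contigs) {
  si <- as_contigs(contigs)
  red <- reduce(granges(tes), ignore.strand = TRUE)
  seqlevels(red) <- seqlevels(si)
  suppressWarnings(seqinfo(red) <- si)
  red <- GenomicRanges::trim(red) # clip annotations that overrun contig ends
  cvg <- coverage(red)
  cvg > 0L
}

#' TE density of genomic windows
#'
#' Fraction of each window's bases covered by the merged union of TE
#' annotations (overlapping and nested elements are merged first, so no base
#' counts twice). This base-pair coverage fraction is the operational
#' definition of "TE density" used throughout the package.
#'
#' @param windows A `GRanges` of windows.
#' @param tes A `GRanges` of TE annotations, or a precomputed [te_coverage()]
#'   `RleList` (much faster for many queries).
#' @return Numeric vector of fractions in `[0, 1]`, parallel to `windows`.
#' @examples
#' w <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
#' te <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 41), c(60, 100)))
#' coverage_fraction(w, te) # fully covered after merging
#' @export
coverage_fraction <- function(windows, tes) {
  stopifnot(is(windows, "GRanges"), length(windows) >= 1L)
  if (is(tes, "RleList")) {
    covbp <- numeric(length(windows))
    sn <- as.character(seqnames(windows))
    for (chr in unique(sn)) {
      idx <- which(sn == chr)
      if (!chr %in% names(tes)) next
      v <- Views(tes[[chr]], ranges(windows)[idx])
      covbp[idx] <- sum(v)
    }
    return(covbp / width(windows))
  }
  red <- reduce(granges(tes), ignore.strand = TRUE)
  hits <- findOverlaps(windows, red, ignore.strand = TRUE)
  ov <- pintersect(ranges(windows)[queryHits(hits)],
                   ranges(red)[subjectHits(hits)])
  covbp <- numeric(length(windows))
  if (length(hits)) {
    agg <- tapply(width(ov), queryHits(hits), sum)
    covbp[as.integer(names(agg))] <- as.numeric(agg)
  }
  covbp / width(windows)
}

#' Sample random genomic windows
#'
#' Draws `n` windows of exactly `width` bp, each fully inside a contig, with
#' start positions uniform over all eligible positions pooled across contigs
#' (a contig is chosen with probability proportional to its number of valid
#' start positions, `length - width + 1`). Windows may overlap one another.
#' This is the resampling step behind the permutation null.
#'
#' @param contigs Contig lengths (see [expand_to_window()]).
#' @param width Window width in bp.
#' @param n Number of windows.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   windows and the caller's RNG stream is left untouched.
#' @param exclude Optional `GRanges` mask (e.g. assembly gaps / N runs):
#'   windows overlapping it are rejected and redrawn. Masking is off by
#'   default.
#' @return A `GRanges` of `n` unstranded windows.
#' @export
sample_random_windows <- function(contigs, width, n, seed = NULL,
                                  exclude = NULL) {
  si <- as_contigs(contigs)
  width <- as.integer(width)
  n <- as.integer(n)
  stopifnot(width >= 1L, n >= 0L)
  lens <- seqlengths(si)
  elig <- pmax(as.double(lens) - width + 1, 0)
  if (all(elig == 0)) {
    stop("no contig can host a window of width ", width)
  }
  if (n == 0L) {
    return(GRanges(seqinfo = si))
  }
  with_seed(seed, {
    draw <- function(m) {
      ci <- sample.int(length(lens), m, replace = TRUE, prob = elig)
      starts <- floor(runif(m) * elig[ci]) + 1
      GRanges(names(lens)[ci], IRanges(as.integer(starts),
                                       width = width), seqinfo = si)
    }
    out <- draw(n)
    if (!is.null(exclude)) {
      for (tries in seq_len(1000L)) {
        bad <- overlapsAny(out, exclude, ignore.strand = TRUE)
        if (!any(bad)) break
        out[bad] <- draw(sum(bad))
      }
      if (any(overlapsAny(out, exclude, ignore.strand = TRUE))) {
        stop("could not sample ", n, " windows avoiding the exclusion mask")
      }
    }
    out
  })
}

#' Strand-oriented binned TE density of a window
#'
#' Splits a window into `bin_bp` bins and returns the TE coverage fraction of
#' each bin, ordered 5' to 3' along the gene: for a minus-strand gene the
#' genomic bin order is reversed, so bin index always increases in the gene's
#' direction of transcription. Unstranded genes are profiled as plus strand,
#' with a warning.
#'
#' @param window A single-range `GRanges` window.
#' @param gene The gene the window belongs to (`GRanges`; only its strand is
#'   used), or a strand given as `"+"`/`"-"`.
#' @param tes TE annotations (`GRanges` or [te_coverage()] `RleList`).
#' @param spec A [window_spec()]; only `bin_bp` is used.
#' @return Numeric vector of `width(window)/bin_bp` coverage fractions.
#' @export
binned_coverage <- function(window, gene, tes, spec = window_spec()) {
  stopifnot(is(window, "GRanges"), length(window) == 1L)
  bin <- spec$bin_bp
  if (width(window) %% bin != 0L) {
    stop("window width ", width(window), " not divisible by bin_bp ", bin)
  }
  strand_chr <- if (is(gene, "GRanges")) as.character(strand(gene))[1]
                else as.character(gene)
  if (!strand_chr %in% c("+", "-")) {
    warning("unstranded gene: profiling as plus strand")
    strand_chr <- "+"
  }
  nb <- width(window) %/% bin
  bins <- GRanges(seqnames(window),
                  IRanges(start = start(window) + (seq_len(nb) - 1L) * bin,
                          width = bin))
  v <- coverage_fraction(bins, tes)
  if (strand_chr == "-") rev(v) else v
}

# Binned coverage for many equal-width windows at once; returns a matrix of
# n_windows x n_bins fractions, rows strand-oriented per `strands`.
binned_coverage_matrix <- function(windows, strands, tes, bin_bp) {
  stopifnot(length(unique(width(windows))) == 1L)
  w <- width(windows)[1]
  if (w %% bin_bp != 0L) stop("window width not divisible by bin_bp")
  nb <- w %/% bin_bp
  n <- length(windows)
  offs <- (seq_len(nb) - 1L) * bin_bp
  bins <- GRanges(rep(seqnames(windows), each = nb),
                  IRanges(rep(start(windows), each = nb) + rep(offs, n),
                          width = bin_bp))
  v <- coverage_fraction(bins, tes)
  m <- matrix(v, nrow = n, ncol = nb, byrow = TRUE)
  flip <- strands == "-"
  if (any(flip)) m[flip, ] <- m[flip, nb:1, drop = FALSE]
  m
}

## --- annotation IO ----------------------------------------------------------

#' Read gene models from GFF3 or BED12
#'
#' For GFF3, the gene/mRNA/exon hierarchy is resolved via `Parent` attributes
#' (exon features are required); for BED12, exons are taken from the block
#' structure. The result is the package's working representation of gene
#' models: a `GRanges` of gene spans with metadata columns `gene_id`,
#' `family` (from the GFF3 `family` attribute or BED name prefix, `NA` when
#' absent) and an `exons` `GRangesList` column sorted by genomic start.
#'
#' @param file Path to a `.gff3`/`.gff` or `.bed` file.
#' @return A `GRanges` with metadata columns `gene_id`, `family`, `exons`.
#' @export
read_gene_models <- function(file) {
  fmt <- tolower(tools::file_ext(sub("\\.gz$", "", file)))
  if (fmt %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(file, format = "gff3")
    genes <- gr[gr$type == "gene"]
    mrna <- gr[gr$type == "mRNA"]
    exons <- gr[gr$type == "exon"]
    mrna_parent <- setNames(unlist(mrna$Parent), mrna$ID)
    exon_tx <- unlist(exons$Parent)
    exon_gene <- ifelse(exon_tx %in% names(mrna_parent),
                        mrna_parent[exon_tx], exon_tx)
    ex_by_gene <- split(granges(exons), factor(exon_gene, levels = genes$ID))
    ex_by_gene <- endoapply(ex_by_gene, sort)
    out <- granges(genes)
    mcols(out)$gene_id <- genes$ID
    fam <- if (!is.null(genes$family)) as.character(genes$family)
           else rep(NA_character_, length(genes))
    mcols(out)$family <- fam
    mcols(out)$exons <- ex_by_gene
    names(out) <- out$gene_id
    return(out)
  }
  if (fmt == "bed") {
    gr <- rtracklayer::import(file, format = "bed")
    out <- granges(gr)
    mcols(out)$gene_id <- gr$name
    mcols(out)$family <- rep(NA_character_, length(gr))
    if (!is.null(gr$blocks)) {
      ex <- unlist(gr$blocks)
      ex <- shift(ex, rep(start(gr) - 1L, lengths(gr$blocks)))
      exg <- GRanges(rep(seqnames(gr), lengths(gr$blocks)), ex)
      mcols(out)$exons <- split(exg, rep(seq_along(gr), lengths(gr$blocks)))
    } else {
      mcols(out)$exons <- as(split(granges(gr), seq_along(gr)), "GRangesList")
    }
    names(out) <- out$gene_id
    return(out)
  }
  stop("unsupported gene model format: ", fmt)
}

#' Write gene models as GFF3
#'
#' Emits a gene/mRNA/exon hierarchy (one transcript per gene) compatible with
#' [read_gene_models()].
#'
#' @param genes A `GRanges` with `gene_id`, optional `family`, and an `exons`
#'   `GRangesList` column.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, file) {
  stopifnot(!is.null(genes$gene_id), !is.null(genes$exons))
  n <- length(genes)
  ex <- genes$exons
  nex <- lengths(ex)
  decorate <- function(gr, type, id, parent, family) {
    gr <- granges(gr)
    mcols(gr) <- DataFrame(
      type = type, ID = id,
      Parent = as(as.list(parent), "CharacterList"),
      family = family)
    gr
  }
  g <- decorate(genes, "gene", genes$gene_id,
                rep(list(character(0)), n),
                if (is.null(genes$family)) rep(NA_character_, n)
                else genes$family)
  m <- decorate(genes, "mRNA", paste0(genes$gene_id, ".t1"),
                as.list(genes$gene_id), rep(NA_character_, n))
  e <- unlist(ex, use.names = FALSE)
  strand(e) <- rep(strand(genes), nex)
  e <- decorate(e, "exon",
                paste0(rep(genes$gene_id, nex), ".e",
                       unlist(lapply(nex, seq_len))),
                as.list(rep(paste0(genes$gene_id, ".t1"), nex)),
                rep(NA_character_, sum(nex)))
  all <- c(g, m, e)
  mcols(all)$source <- "tefam"
  rtracklayer::export(all, file, format = "gff3")
  invisible(file)
}

#' Read TE annotations from BED6 or GFF3
#'
#' BED6: the `name` column carries the TE family label and `strand` the
#' element orientation. GFF3: the family is read from `family_attr`
#' (default `"Classification"`).
#'
#' @param file Path to a `.bed` or `.gff3`/`.gff` file.
#' @param family_attr GFF3 attribute key holding the family label.
#' @return A `GRanges` with metadata columns `family` and `element_id`.
#' @export
read_te_annotations <- function(file, family_attr = "Classification") {
  fmt <- tolower(tools::file_ext(sub("\\.gz$", "", file)))
  if (fmt == "bed") {
    gr <- rtracklayer::import(file, format = "bed")
    out <- granges(gr)
    mcols(out)$family <- gr$name
    mcols(out)$element_id <- paste0("te_", seq_along(gr))
    return(out)
  }
  if (fmt %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(file, format = "gff3")
    out <- granges(gr)
    fam <- mcols(gr)[[family_attr]]
    if (is.null(fam)) stop("GFF3 lacks family attribute '", family_attr, "'")
    mcols(out)$family <- as.character(fam)
    id <- gr$ID
    mcols(out)$element_id <- if (is.null(id)) paste0("te_", seq_along(gr))
                             else as.character(id)
    return(out)
  }
  stop("unsupported TE annotation format: ", fmt)
}

#' Write TE annotations as BED6
#'
#' @param tes A `GRanges` with a `family` metadata column.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_te_bed <- function(tes, file) {
  out <- granges(tes)
  mcols(out)$name <- if (!is.null(tes$family)) tes$family
                     else rep(".", length(tes))
  mcols(out)$score <- 0L
  rtracklayer::export(out, file, format = "bed")
  invisible(file)
}

#' Write windows (or any interval set) as BED6
#' @param windows A `GRanges`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_windows_bed <- function(windows, file) {
  out <- granges(windows)
  nm <- names(windows)
  mcols(out)$name <- if (is.null(nm)) paste0("w", seq_along(windows)) else nm
  mcols(out)$score <- 0L
  rtracklayer::export(out, file, format = "bed")
  invisible(file)
}

#' Write per-window TE densities as TSV
#' @param windows A `GRanges` of measured windows.
#' @param densities Numeric vector parallel to `windows`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_density_tsv <- function(windows, densities, file) {
  df <- data.frame(contig = as.character(seqnames(windows)),
                   start = start(windows), end = end(windows),
                   width = width(windows),
                   name = if (is.null(names(windows)))
                            paste0("w", seq_along(windows)) else names(windows),
                   te_density = densities)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
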