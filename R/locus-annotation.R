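## Candidate locus discovery by exon-level Smith-Waterman homology and
## gene/pseudogene classification by integrity rules (all exons present, no
## frameshift indels, no nonsense mutations).

.sw_cache <- new.env(parent = emptyenv())

sw_matrix <- function() {
  if (is.null(.sw_cache$mat)) {
    .sw_cache$mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  }
  .sw_cache$mat
}

# Exact k-mer seed index over all reference exons on both strands; built once
# and reused across contigs. PDict construction is the expensive step, so
# annotate_genome shares one index for the whole genome.
build_seed_index <- function(exons, seed_k = 12L, seed_step = 4L) {
  pats <- list(); map <- list()
  for (k in seq_along(exons)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") exons[k] else
        as.character(reverseComplement(DNAString(exons[k])))
      plen <- nchar(pat)
      kk <- min(seed_k, plen)
      offs <- unique(c(seq(1L, plen - kk + 1L, by = seed_step),
                       plen - kk + 1L))
      pats[[paste0(k, str)]] <- pat
      map[[paste0(k, str)]] <- data.frame(
        exon = k, strand = str, off = offs,
        kmer = substring(pat, offs, offs + kk - 1L))
    }
  }
  map <- do.call(rbind, map)
  kmers <- DNAStringSet(map$kmer)
  structure(list(pdict = PDict(kmers), map = map, patterns = pats,
                 seed_k = seed_k, seed_step = seed_step),
            class = "seed_index")
}

# Vectorised alignment acceptance for SW hits of `pat` inside candidate
# subject `regions` (IRanges on the contig). Identity = matches / aligned
# columns including gaps; a hit must cover >= 50% of the reference exon.
sw_candidates <- function(subject, pat, regions, min_identity) {
  plen <- nchar(pat)
  res <- data.frame(start = integer(), end = integer(), identity = numeric(),
                    columns = integer(), gaps = integer(), score = numeric())
  if (!length(regions)) return(res)
  segs <- DNAStringSet(Views(subject, regions))
  aln <- pairwiseAlignment(segs, DNAString(pat), type = "local",
                           substitutionMatrix = sw_matrix(),
                           gapOpening = 2, gapExtension = 1)
  cols <- nchar(aln)
  ident <- nmatch(aln) / cols
  ni <- Biostrings::nindel(aln)
  gaps <- Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  sal <- Biostrings::subject(aln) # aligned range of the reference exon
  sub_bases <- end(sal) - start(sal) + 1L
  ok <- ident >= min_identity & sub_bases >= 0.5 * plen
  if (!any(ok)) return(res)
  pr <- Biostrings::pattern(aln) # aligned part of each candidate region
  data.frame(start = start(regions)[ok] + start(pr)[ok] - 1L,
             end = start(regions)[ok] + end(pr)[ok] - 1L,
             identity = ident[ok], columns = cols[ok],
             gaps = as.integer(gaps[ok]), score = score(aln)[ok])
}

# Cluster implied pattern starts into candidate regions and confirm by SW.
seeds_to_hits <- function(subject, pat, starts, min_identity) {
  plen <- nchar(pat)
  if (!length(starts)) {
    return(data.frame(start = integer(), end = integer(),
                      identity = numeric(), columns = integer(),
                      gaps = integer(), score = numeric()))
  }
  starts <- sort(starts)
  grp <- cumsum(c(1L, as.integer(diff(starts) > plen %/% 2L)))
  margin <- max(20L, plen %/% 5L)
  lo <- vapply(split(starts, grp), min, numeric(1))
  hi <- vapply(split(starts, grp), max, numeric(1))
  regions <- reduce(IRanges(pmax(1L, as.integer(lo) - margin),
                            pmin(length(subject),
                                 as.integer(hi) + plen + margin)))
  sw_candidates(subject, pat, regions, min_identity)
}

# Full-contig SW with recursive masking: align, record qualifying hit, then
# recurse into the flanks. Oracle-grade but O(contig x exon) per call.
sw_exhaustive <- function(subject, pat, min_identity) {
  plen <- nchar(pat)
  res <- data.frame(start = integer(), end = integer(), identity = numeric(),
                    columns = integer(), gaps = integer(), score = numeric())
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < ceiling(0.5 * plen)) return()
    hit <- sw_candidates(subject, pat, IRanges(lo, hi), min_identity)
    if (nrow(hit) == 0L) return()
    res <<- rbind(res, hit)
    recurse(lo, hit$start[1] - 1L)
    recurse(hit$end[1] + 1L, hi)
  }
  recurse(1L, length(subject))
  res[order(res$start), , drop = FALSE]
}

#' Scan a contig for exon-level homology to a reference gene
#'
#' Finds local Smith-Waterman alignments (match +1, mismatch -1, gap open 2,
#' gap extend 1; Biostrings convention, an L-long gap costs
#' `open + L * extend`) of each reference exon against both strands of the
#' contig, and reports every non-overlapping hit with identity at least
#' `min_identity` (identity = matches / aligned columns including gaps) whose
#' alignment covers at least half of the reference exon.
#'
#' `method = "seed"` (default) restricts Smith-Waterman to candidate regions
#' anchored by exact k-mer seed matches — a pure speedup that makes
#' whole-genome scans desk-scale; `method = "exhaustive"` aligns against the
#' full contig with recursive masking and serves as the oracle in tests.
#'
#' @param subject Contig sequence (`DNAString` or character).
#' @param ref_exons Reference exon sequences, 5' to 3' (character vector or
#'   `DNAStringSet`); each must be at least 20 bp.
#' @param min_identity Identity threshold (default 0.80).
#' @param contig_name Contig label for the output coordinates.
#' @param method `"seed"` or `"exhaustive"`.
#' @param seed_k,seed_step Seed k-mer length and spacing for `"seed"` mode.
#' @param seed_index Optional prebuilt index from repeated scans of the same
#'   reference (internal use by [annotate_genome()]).
#' @return A `GRanges` of hits sorted by contig position, with metadata
#'   `ref_exon_index`, `percent_identity`, `aligned_columns`, `indel_bp`,
#'   `score`; strand gives the gene orientation of the hit.
#' @export
scan_exon_homology <- function(subject, ref_exons, min_identity = 0.80,
                               contig_name = "contig",
                               method = c("seed", "exhaustive"),
                               seed_k = 12L, seed_step = 4L,
                               seed_index = NULL) {
  method <- match.arg(method)
  subject <- DNAString(as.character(subject))
  exons <- as.character(ref_exons)
  if (any(nchar(exons) < 20L)) stop("reference exons must be >= 20 bp")
  if (length(subject) < min(nchar(exons))) {
    return(empty_hits())
  }
  out <- GRanges()
  if (method == "seed") {
    if (is.null(seed_index)) {
      seed_index <- build_seed_index(exons, seed_k, seed_step)
    }
    mt <- matchPDict(seed_index$pdict, subject)
    mstarts <- Biostrings::startIndex(mt)
    keys <- paste0(seed_index$map$exon, seed_index$map$strand)
    for (key in names(seed_index$patterns)) {
      rows <- which(keys == key)
      starts <- unlist(lapply(rows, function(j) {
        s <- mstarts[[j]]
        if (is.null(s)) integer(0) else s - (seed_index$map$off[j] - 1L)
      }), use.names = FALSE)
      hits <- seeds_to_hits(subject, seed_index$patterns[[key]], starts,
                            min_identity)
      out <- add_hits(out, hits, contig_name,
                      seed_index$map$exon[rows[1]],
                      seed_index$map$strand[rows[1]])
    }
  } else {
    for (k in seq_along(exons)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") exons[k] else
          as.character(reverseComplement(DNAString(exons[k])))
        hits <- sw_exhaustive(subject, pat, min_identity)
        out <- add_hits(out, hits, contig_name, k, str)
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  # drop lower-scoring hits of the same exon overlapping a better one
  keep <- rep(TRUE, length(out))
  st <- start(out); en <- end(out)
  for (k in unique(out$ref_exon_index)) {
    idx <- which(out$ref_exon_index == k)
    o <- idx[order(-out$score[idx])]
    ts <- numeric(0); te <- numeric(0)
    for (i in o) {
      if (length(ts) && any(st[i] <= te & en[i] >= ts)) {
        keep[i] <- FALSE
      } else {
        ts <- c(ts, st[i]); te <- c(te, en[i])
      }
    }
  }
  sort(out[keep], ignore.strand = TRUE)
}

add_hits <- function(out, hits, contig_name, exon_index, strand_chr) {
  if (nrow(hits) == 0L) return(out)
  gr <- GRanges(contig_name, IRanges(hits$start, hits$end),
                strand = strand_chr)
  mcols(gr)$ref_exon_index <- exon_index
  mcols(gr)$percent_identity <- hits$identity
  mcols(gr)$aligned_columns <- hits$columns
  mcols(gr)$indel_bp <- hits$gaps
  mcols(gr)$score <- hits$score
  c(out, gr)
}

empty_hits <- function() {
  gr <- GRanges()
  mcols(gr)$ref_exon_index <- integer(0)
  mcols(gr)$percent_identity <- numeric(0)
  mcols(gr)$aligned_columns <- integer(0)
  mcols(gr)$indel_bp <- integer(0)
  mcols(gr)$score <- numeric(0)
  gr
}

#' Group exon hits into candidate family loci
#'
#' Chains hits from one contig that lie on the same strand, have ascending
#' reference-exon index in gene orientation, and are separated by at most
#' `max_gap_bp`. A chain qualifies as a candidate locus when it contains at
#' least `min_consecutive` hits with consecutive reference-exon indices.
#' Chimeric or duplicated exon arrangements break the ascending-index rule
#' and are therefore reported as separate loci, never merged.
#'
#' @param hits A [scan_exon_homology()] `GRanges` (one contig).
#' @param min_consecutive Minimum run of consecutive exon indices (default 2).
#' @param max_gap_bp Maximum genomic gap between chained hits (default
#'   20000, the intron/intergenic scale of multi-kb loci).
#' @return A list of `family_locus` objects (`span`, `strand`, `hits`).
#' @export
select_candidate_loci <- function(hits, min_consecutive = 2L,
                                  max_gap_bp = 20000L) {
  if (length(hits) == 0L) return(list())
  if (length(unique(as.character(seqnames(hits)))) > 1L) {
    stop("hits span multiple contigs; chain per contig")
  }
  loci <- list()
  for (str in c("+", "-")) {
    h <- hits[strand(hits) == str]
    if (!length(h)) next
    h <- h[order(start(h))]
    chains <- list(); cur <- integer(0)
    for (i in seq_along(h)) {
      if (!length(cur)) { cur <- i; next }
      prev <- cur[length(cur)]
      gap <- start(h)[i] - end(h)[prev]
      idx_ok <- if (str == "+") {
        h$ref_exon_index[i] > h$ref_exon_index[prev]
      } else {
        h$ref_exon_index[i] < h$ref_exon_index[prev]
      }
      if (gap <= max_gap_bp && idx_ok) {
        cur <- c(cur, i)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- i
      }
    }
    if (length(cur)) chains[[length(chains) + 1L]] <- cur
    for (ch in chains) {
      idxs <- h$ref_exon_index[ch]
      ord <- if (str == "+") idxs else rev(idxs)
      if (max_consecutive_run(ord) >= min_consecutive) {
        hh <- h[ch]
        span <- GRanges(seqnames(hh)[1],
                        IRanges(min(start(hh)), max(end(hh))), strand = str)
        loci[[length(loci) + 1L]] <- structure(
          list(span = span, strand = str,
               hits = hh[order(hh$ref_exon_index)]),
          class = "family_locus")
      }
    }
  }
  ord <- order(vapply(loci, function(l) start(l$span), numeric(1)))
  loci[ord]
}

# Longest run of +1 increments in an integer sequence.
max_consecutive_run <- function(v) {
  if (!length(v)) return(0L)
  best <- 1L; cur <- 1L
  for (i in seq_along(v)[-1]) {
    if (v[i] == v[i - 1] + 1L) cur <- cur + 1L else cur <- 1L
    best <- max(best, cur)
  }
  best
}

## --- classification ---------------------------------------------------------

# Batched integrity classification. `entries` is a list of
# list(locus = family_locus, subject = DNAString). For every present exon
# the hit region (plus margin) is extracted in gene orientation and aligned
# end-to-end against the reference exon (exon side global), batched across
# loci per exon so a whole-genome classification costs one pairwiseAlignment
# call per reference exon. Uncovered exon ends count as deletions.
classify_engine <- function(entries, ref) {
  nex <- length(ref$exon_seqs)
  n <- length(entries)
  exon_status <- matrix("present", nrow = n, ncol = nex)
  region_str <- matrix("", nrow = n, ncol = nex)
  for (i in seq_len(n)) {
    locus <- entries[[i]]$locus
    contig <- entries[[i]]$subject
    lo <- integer(0); hi <- integer(0); kk <- integer(0)
    for (k in seq_len(nex)) {
      hk <- locus$hits[locus$hits$ref_exon_index == k]
      if (!length(hk)) {
        exon_status[i, k] <- "missing"
        next
      }
      hk <- hk[which.max(hk$percent_identity)]
      # the SW hit may be end-trimmed (terminal mismatch runs); extend the
      # region so the exon-global re-alignment can always cover the full exon
      margin <- 30L + max(0L, nchar(ref$exon_seqs[k]) - width(hk))
      lo <- c(lo, max(1L, start(hk) - margin))
      hi <- c(hi, min(length(contig), end(hk) + margin))
      kk <- c(kk, k)
    }
    if (!length(kk)) next
    v <- DNAStringSet(Views(contig, IRanges(lo, hi)))
    if (locus$strand == "-") v <- reverseComplement(v)
    region_str[i, kk] <- as.character(v)
  }
  indel <- matrix(0L, nrow = n, ncol = nex)
  cds_part <- matrix("", nrow = n, ncol = nex)
  for (k in seq_len(nex)) {
    idxs <- which(exon_status[, k] == "present")
    if (!length(idxs)) next
    exon_len <- nchar(ref$exon_seqs[k])
    # stiffer gap penalties than the discovery scan: a true frameshift indel
    # still wins by a large margin (it rescues the downstream frame), while
    # spurious single-base gaps that substitution noise can make marginally
    # optimal under the scan scoring are suppressed
    aln <- pairwiseAlignment(DNAStringSet(region_str[idxs, k]),
                             DNAString(ref$exon_seqs[k]),
                             type = "local-global",
                             substitutionMatrix = sw_matrix(),
                             gapOpening = 6, gapExtension = 2)
    ni <- Biostrings::nindel(aln)
    gaps <- Biostrings::insertion(ni)[, "WidthSum"] +
      Biostrings::deletion(ni)[, "WidthSum"]
    pr <- Biostrings::pattern(aln)
    sal <- Biostrings::subject(aln)
    covered <- end(sal) - start(sal) + 1L
    indel[idxs, k] <- as.integer(gaps + (exon_len - covered))
    # the aligned pattern, degapped, is a contiguous slice of the region
    cds_part[idxs, k] <- substring(region_str[idxs, k], start(pr), end(pr))
  }
  spliced <- vapply(seq_len(n), function(i)
    paste(cds_part[i, exon_status[i, ] == "present"], collapse = ""),
    character(1))
  ntr <- 3L * (nchar(spliced) %/% 3L)
  translation <- as.character(suppressWarnings(
    translate(DNAStringSet(substr(spliced, 1, ntr)), if.fuzzy.codon = "X")))
  lapply(seq_len(n), function(i) {
    locus <- entries[[i]]$locus
    reasons <- character(0)
    if (any(exon_status[i, ] == "missing")) reasons <- c(reasons, "missing_exon")
    if (any(indel[i, ] %% 3L != 0L)) reasons <- c(reasons, "frameshift_indel")
    tr <- translation[i]
    if (nchar(tr)) {
      stars <- gregexpr("*", tr, fixed = TRUE)[[1]]
      stars <- stars[stars > 0]
      if (any(stars < nchar(tr))) {
        reasons <- c(reasons, "premature_stop")
      }
      if (!length(stars) || max(stars) != nchar(tr)) {
        reasons <- c(reasons, "no_terminal_stop")
      }
    } else {
      reasons <- c(reasons, "no_terminal_stop")
    }
    structure(list(span = locus$span, strand = locus$strand,
                   classification = if (length(reasons)) "pseudogene"
                                    else "gene",
                   reasons = reasons, exon_status = exon_status[i, ],
                   indel_by_exon = indel[i, ],
                   spliced_cds = spliced[i], translation = tr,
                   hits = locus$hits),
              class = "locus_call")
  })
}

#' Classify a candidate locus as gene or pseudogene
#'
#' Applies the integrity rules to a candidate locus: `missing_exon` when any
#' of the reference exons lacks a qualifying hit; `frameshift_indel` when the
#' total indel length within any exon's alignment is not a multiple of 3;
#' `premature_stop` when the conceptual translation of the spliced candidate
#' CDS contains a stop before its final codon; `no_terminal_stop` when the
#' translation does not end in a stop. The locus is a `gene` iff no reason
#' fires — in particular, in-frame indels alone do not pseudogenize.
#'
#' For each present exon the hit region (plus a small margin) is re-aligned
#' end-to-end against the reference exon (exon-global alignment), so
#' terminal exon mismatches cannot silently truncate the candidate CDS.
#'
#' @param locus A `family_locus` from [select_candidate_loci()].
#' @param subject The contig sequence (`DNAString` or character) the locus
#'   lives on.
#' @param ref A [reference_gene()] model.
#' @return A `locus_call` list: `span`, `strand`, `classification`,
#'   `reasons`, `exon_status` (per reference exon), `spliced_cds`,
#'   `translation`, `hits`.
#' @export
classify_locus <- function(locus, subject, ref) {
  stopifnot(inherits(locus, "family_locus"), inherits(ref, "ref_gene"))
  subject <- DNAString(as.character(subject))
  classify_engine(list(list(locus = locus, subject = subject)), ref)[[1]]
}

#' @export
print.locus_call <- function(x, ...) {
  cat("locus", as.character(seqnames(x$span)), paste0(start(x$span), "-",
      end(x$span)), x$strand, "->", x$classification)
  if (length(x$reasons)) cat(" (", paste(x$reasons, collapse = ","), ")")
  cat("\n")
  invisible(x)
}

#' Discover and classify family loci across a genome
#'
#' Runs [scan_exon_homology()], [select_candidate_loci()] and
#' [classify_locus()] on every contig (sharing the seed index and batching
#' the classification alignments) and collects the results.
#'
#' @param genome A named `DNAStringSet`.
#' @param ref A [reference_gene()]-style model (a list with `exon_seqs`).
#' @param min_identity,min_consecutive,max_gap_bp,method See the stage
#'   functions.
#' @return An `annotation_result` list: `calls` (list of `locus_call`),
#'   `summary` (data.frame: `locus_id`, `contig`, `start`, `end`, `strand`,
#'   `classification`, `reasons`, `n_exons_hit`) and `loci` (`GRanges`).
#' @export
annotate_genome <- function(genome, ref = reference_gene(),
                            min_identity = 0.80, min_consecutive = 2L,
                            max_gap_bp = 20000L,
                            method = c("seed", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  idx <- if (method == "seed") build_seed_index(ref$exon_seqs) else NULL
  entries <- list()
  for (chr in names(genome)) {
    subject <- genome[[chr]]
    hits <- scan_exon_homology(subject, ref$exon_seqs, min_identity,
                               contig_name = chr, method = method,
                               seed_index = idx)
    loci <- select_candidate_loci(hits, min_consecutive, max_gap_bp)
    for (lc in loci) {
      entries[[length(entries) + 1L]] <- list(locus = lc, subject = subject)
    }
  }
  calls <- if (length(entries)) classify_engine(entries, ref) else list()
  if (length(calls)) {
    summary <- data.frame(
      locus_id = sprintf("locus%03d", seq_along(calls)),
      contig = vapply(calls, function(x)
        as.character(seqnames(x$span)), character(1)),
      start = vapply(calls, function(x) start(x$span), numeric(1)),
      end = vapply(calls, function(x) end(x$span), numeric(1)),
      strand = vapply(calls, `[[`, character(1), "strand"),
      classification = vapply(calls, `[[`, character(1), "classification"),
      reasons = vapply(calls, function(x)
        paste(x$reasons, collapse = ","), character(1)),
      n_exons_hit = vapply(calls, function(x)
        sum(x$exon_status == "present"), numeric(1)))
    loci <- GRanges(summary$contig, IRanges(summary$start, summary$end),
                    strand = summary$strand)
    names(loci) <- summary$locus_id
    mcols(loci)$classification <- summary$classification
  } else {
    summary <- data.frame(locus_id = character(0), contig = character(0),
                          start = numeric(0), end = numeric(0),
                          strand = character(0), classification = character(0),
                          reasons = character(0), n_exons_hit = numeric(0))
    loci <- GRanges()
  }
  structure(list(calls = calls, summary = summary, loci = loci),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("annotation_result:", nrow(x$summary), "loci (",
      sum(x$summary$classification == "gene"), "genes /",
      sum(x$summary$classification == "pseudogene"), "pseudogenes )\n")
  invisible(x)
}

#' Write locus calls as GFF3 + reasons TSV
#'
#' @param ann An [annotate_genome()] result.
#' @param prefix Output prefix (writes `<prefix>.gff3`, `<prefix>.tsv`).
#' @return The GFF3 path, invisibly.
#' @export
write_locus_calls <- function(ann, prefix) {
  gr <- ann$loci
  if (length(gr)) {
    mcols(gr)$type <- ifelse(ann$summary$classification == "gene",
                             "gene", "pseudogene")
    mcols(gr)$ID <- ann$summary$locus_id
    mcols(gr)$source <- "tefam"
    mcols(gr)$reasons <- ann$summary$reasons
  }
  rtracklayer::export(gr, paste0(prefix, ".gff3"), format = "gff3")
  write.table(ann$summary, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, ".gff3"))
}
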