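## Synthetic genomes with planted paralog clusters, lesions and TE landscapes.
## Everything downstream (locus discovery, integrity classification, TE
## enrichment, motif classification) is validated against the ground truth
## these generators record.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# One fixed codon per amino acid (used to reverse-translate the reference
# protein into a reference CDS; divergence is applied at the nucleotide level
# afterwards, so codon usage realism is not needed).
AA_TO_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## --- synthetic IDS protein panel -------------------------------------------

# Segment layout of the synthetic canonical IDS protein: linkers interleaved
# with motifs in their canonical order; FARM->SARM start separation is 99
# residues (>= the 80-residue assignment rule). Total length 404 aa.
panel_layout <- function() {
  list(c("linker", 20), c("IGM1", NA), c("linker", 15), c("IGM2", NA),
       c("linker", 15), c("IGM3", NA), c("linker", 10), c("FARM", NA),
       c("linker", 12), c("IGM4", NA), c("linker", 20), c("IGM5", NA),
       c("linker", 30), c("IGM6", NA), c("linker", 20), c("SARM", NA),
       c("linker", 218))
}

# Build one synthetic protein; `present` names the motifs planted intact,
# the remaining motif slots are filled with linker residues. Linkers avoid D
# entirely, so the only DDxxD matches are the planted FARM/SARM. The result
# is verified against scan_motif and linkers resampled on (rare) spurious
# matches.
build_panel_protein <- function(motifs, present = names(motifs),
                                max_tries = 50L) {
  linker_aa <- setdiff(AA20, "D")
  layout <- panel_layout()
  for (try in seq_len(max_tries)) {
    parts <- lapply(layout, function(seg) {
      if (seg[1] == "linker") {
        paste(sample(linker_aa, as.integer(seg[2]), replace = TRUE),
              collapse = "")
      } else {
        m <- motifs[[seg[1]]]
        if (seg[1] %in% present) {
          motif_consensus_seq(m)
        } else {
          paste(sample(linker_aa, length(m$columns), replace = TRUE),
                collapse = "")
        }
      }
    })
    prot <- paste(unlist(parts), collapse = "")
    substr(prot, 1, 1) <- "M"
    ok <- TRUE
    for (nm in names(motifs)) {
      if (nm %in% c("FARM", "SARM")) next
      found <- nrow(scan_motif(prot, motifs[[nm]])) > 0L
      if (found != (nm %in% present)) { ok <- FALSE; break }
    }
    if (ok) {
      nhits <- nrow(scan_motif(prot, motifs$FARM))
      want <- sum(c("FARM", "SARM") %in% present)
      if (nhits != want) ok <- FALSE
    }
    if (ok) return(prot)
  }
  stop("failed to build a clean synthetic panel protein")
}

#' Simulate a labelled IDS protein panel
#'
#' Generates synthetic proteins with known motif content for validating the
#' motif classifier: `canonical` proteins carry FARM, SARM and all six IGMs;
#' `divergent_like` proteins carry only FARM and IGM3 (the conservation
#' pattern of the divergent clade); `indeterminate` proteins lack FARM.
#' Optional per-residue substitution noise degrades the motifs.
#'
#' @param n_per_class Proteins per class.
#' @param noise Per-residue substitution probability applied after
#'   construction (0 = clean panel).
#' @param seed Optional integer seed.
#' @param motifs Motif set (default [built_in_motifs()]).
#' @return A list with `proteins` (named character vector) and `truth`
#'   (data.frame of `id`, `class`).
#' @export
simulate_protein_panel <- function(n_per_class = 10L, noise = 0,
                                   seed = NULL, motifs = built_in_motifs()) {
  stopifnot(noise >= 0, noise <= 1)
  classes <- c("canonical", "divergent_like", "indeterminate")
  present_for <- list(
    canonical = names(motifs),
    divergent_like = c("FARM", "IGM3"),
    indeterminate = setdiff(names(motifs), c("FARM", "SARM"))
  )
  with_seed(seed, {
    ids <- character(0); cls <- character(0); seqs <- character(0)
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        p <- build_panel_protein(motifs, present_for[[cl]])
        if (noise > 0) {
          chars <- strsplit(p, "")[[1]]
          hit <- which(runif(length(chars)) < noise)
          for (j in hit) {
            chars[j] <- sample(setdiff(AA20, chars[j]), 1L)
          }
          p <- paste(chars, collapse = "")
        }
        ids <- c(ids, sprintf("%s_%02d", cl, i))
        cls <- c(cls, cl)
        seqs <- c(seqs, p)
      }
    }
    names(seqs) <- ids
    list(proteins = seqs, truth = data.frame(id = ids, class = cls))
  })
}

## --- reference gene model ---------------------------------------------------

#' The built-in reference gene model
#'
#' A deterministic six-exon reference gene for the focal family: all exons
#' fully coding and codon-aligned (lengths 171, 246, 213, 198, 228, 159 bp;
#' 1215 bp = 404 codons + stop), with the encoded protein being the synthetic
#' canonical IDS panel protein (FARM, SARM, IGM1-6 with linkers), so that
#' pipeline runs on simulated genomes exercise the motif classifier on real
#' translations. Introns carry a conserved 10 bp splice context at each end
#' (GT..AG dinucleotides included); intron interiors are randomized per
#' planted copy.
#'
#' @return A `ref_gene` list: `exon_seqs` (6 nucleotide strings), `cds`,
#'   `protein`, `exon_lengths`, `intron_lengths`, `donor10`, `acceptor10`.
#' @export
reference_gene <- function() {
  motifs <- built_in_motifs()
  prot <- with_seed(19150, build_panel_protein(motifs))
  aa <- strsplit(prot, "")[[1]]
  cds <- paste0(paste(AA_TO_CODON[aa], collapse = ""), "TAA")
  exon_lengths <- c(171L, 246L, 213L, 198L, 228L, 159L)
  stopifnot(sum(exon_lengths) == nchar(cds))
  ends <- cumsum(exon_lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  exon_seqs <- substring(cds, starts, ends)
  structure(list(
    exon_seqs = exon_seqs,
    exon_lengths = exon_lengths,
    intron_lengths = c(350L, 420L, 380L, 300L, 410L),
    donor10 = "GTAAGTATCC",
    acceptor10 = "TTTCTTACAG",
    cds = cds,
    protein = prot
  ), class = "ref_gene")
}

#' @export
print.ref_gene <- function(x, ...) {
  cat("reference gene:", length(x$exon_seqs), "exons (",
      paste(x$exon_lengths, collapse = ", "), "bp ), CDS", nchar(x$cds),
      "bp,", nchar(x$protein), "aa\n")
  invisible(x)
}

## --- lesions ----------------------------------------------------------------

#' Describe a pseudogenizing lesion
#'
#' @param kind `"frameshift_indel"`, `"nonsense_substitution"` or
#'   `"exon_deletion"`.
#' @param exon_index 1-based index among the reference exons.
#' @param length Indel length in bp for frameshifts; must not be divisible
#'   by 3.
#' @param op `"del"` or `"ins"` for frameshift indels.
#' @param codon For nonsense substitutions: 1-based codon index within the
#'   exon (`NULL` = middle codon).
#' @return A `lesion` list.
#' @examples
#' lesion("frameshift_indel", exon_index = 3, length = 1)
#' lesion("nonsense_substitution", exon_index = 2)
#' @export
lesion <- function(kind = c("frameshift_indel", "nonsense_substitution",
                            "exon_deletion"),
                   exon_index, length = 1L, op = c("del", "ins"),
                   codon = NULL) {
  kind <- match.arg(kind)
  op <- match.arg(op)
  exon_index <- as.integer(exon_index)
  stopifnot(exon_index >= 1L)
  if (kind == "frameshift_indel") {
    length <- as.integer(length)
    if (length %% 3L == 0L) {
      stop("frameshift indel length must not be divisible by 3")
    }
  }
  structure(list(kind = kind, exon_index = exon_index, length = length,
                 op = op, codon = codon),
            class = "lesion")
}

# Default balanced lesion assignment: cycle the three kinds over interior
# exons.
default_lesions <- function(n) {
  kinds <- c("frameshift_indel", "nonsense_substitution", "exon_deletion")
  exs <- c(3L, 2L, 4L, 5L)
  lapply(seq_len(n), function(i) {
    lesion(kinds[(i - 1L) %% 3L + 1L], exon_index = exs[(i - 1L) %% 4L + 1L])
  })
}

## --- simulation config ------------------------------------------------------

#' Signature TE placement rule
#'
#' Describes the single "signature" element planted near the last exon of
#' every focal locus (emulating a TE family that travels with the gene
#' family), usually antisense to the gene.
#'
#' @param family TE family label.
#' @param offset_bp Distance from the 3' end of the last exon (in gene
#'   orientation) to the element start; may be negative to place the element
#'   over or upstream of the gene's 3' end.
#' @param antisense_prob Probability the element is oriented opposite to its
#'   gene.
#' @param length_bp Element length.
#' @return A `signature_te` list.
#' @export
signature_te <- function(family = "CACTA_TIR", offset_bp = 500L,
                         antisense_prob = 1, length_bp = 2000L) {
  stopifnot(antisense_prob >= 0, antisense_prob <= 1, length_bp >= 1)
  structure(list(family = family, offset_bp = as.integer(offset_bp),
                 antisense_prob = antisense_prob,
                 length_bp = as.integer(length_bp)),
            class = "signature_te")
}

#' Configuration of a synthetic genome
#'
#' Defaults emulate the study conditions of the focal gene-family expansion:
#' 28 family loci (15 intact genes, 13 pseudogenes) in tandem clusters with a
#' mean adjacent spacing of 23 kb, ~5% sequence divergence among paralogs, a
#' TE landscape with 0.43 background base-pair coverage, and a 1.5x TE
#' coverage enrichment inside the 50 kb-padded focal windows.
#'
#' @param seed Integer master seed; all randomness in [simulate_genome()]
#'   derives from it.
#' @param contig_lengths Named (or unnamed) vector of contig lengths in bp.
#' @param gc_content Background GC fraction.
#' @param background_te_density Target merged TE coverage fraction outside
#'   focal windows.
#' @param te_family_mix Named non-negative weights of TE families.
#' @param focal_enrichment_factor Multiplier on realized TE coverage inside
#'   focal windows (>= 0; 1 = no enrichment).
#' @param n_genes,n_pseudogenes Number of intact / lesioned family copies.
#' @param lesion_spec List of [lesion()]s, one per pseudogene (`NULL` = a
#'   balanced default assignment).
#' @param paralog_spacing_mean,paralog_spacing_sd Normal draw (bp) for
#'   start-to-start distance between adjacent cluster members, truncated so
#'   copies never overlap (and at >= 1 kb).
#' @param divergence Per-base substitution probability applied to planted
#'   exons (codon-safe for copies labelled "gene": substitutions creating a
#'   premature stop are resampled, and start/stop codons are protected, so
#'   truth labels stay exact).
#' @param signature_te A [signature_te()] rule, or `NULL` for none.
#' @param cluster_size Family members per tandem cluster.
#' @param cluster_margin_bp Clearance kept between a cluster and contig ends
#'   (leaves room for unclipped 100 kb windows).
#' @param te_length_meanlog,te_length_sdlog Log-normal TE length parameters
#'   (default median 500 bp).
#' @param focal_pad_bp Pad defining the focal windows inside which TE
#'   placement is enriched.
#' @param emit_sequence If `FALSE`, skip nucleotide sequence generation and
#'   emit annotations only (much faster; sufficient for interval statistics).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(ctg1 = 2e6, ctg2 = 2e6,
                                          ctg3 = 1.5e6, ctg4 = 1.5e6),
                       gc_content = 0.4,
                       background_te_density = 0.43,
                       te_family_mix = c(CACTA_TIR = 0.22, Gypsy_LTR = 0.18,
                                         Copia_LTR = 0.14, hAT_TIR = 0.12,
                                         Mariner_TIR = 0.10, LINE_L2 = 0.10,
                                         Helitron = 0.08, MITE = 0.06),
                       focal_enrichment_factor = 1.5,
                       n_genes = 15L, n_pseudogenes = 13L,
                       lesion_spec = NULL,
                       paralog_spacing_mean = 23000,
                       paralog_spacing_sd = 1000,
                       divergence = 0.05,
                       signature_te = NULL,
                       cluster_size = 7L,
                       cluster_margin_bp = 60000L,
                       te_length_meanlog = log(500),
                       te_length_sdlog = 0.75,
                       focal_pad_bp = 50000L,
                       emit_sequence = TRUE) {
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- sprintf("ctg%d", seq_along(contig_lengths))
  }
  stopifnot(all(contig_lengths >= 1),
            gc_content >= 0, gc_content <= 1,
            background_te_density >= 0, background_te_density < 1,
            focal_enrichment_factor >= 0,
            n_genes >= 0, n_pseudogenes >= 0,
            all(te_family_mix >= 0), sum(te_family_mix) > 0,
            divergence >= 0, divergence <= 1,
            paralog_spacing_mean > 0, paralog_spacing_sd >= 0,
            cluster_size >= 1)
  if (is.null(lesion_spec)) lesion_spec <- default_lesions(n_pseudogenes)
  if (length(lesion_spec) != n_pseudogenes) {
    stop("lesion_spec has ", length(lesion_spec), " entries but n_pseudogenes = ",
         n_pseudogenes)
  }
  if (!is.null(signature_te) && !inherits(signature_te, "signature_te")) {
    stop("signature_te must be built with signature_te() or be NULL")
  }
  structure(list(seed = seed, contig_lengths = contig_lengths,
                 gc_content = gc_content,
                 background_te_density = background_te_density,
                 te_family_mix = te_family_mix / sum(te_family_mix),
                 focal_enrichment_factor = focal_enrichment_factor,
                 n_genes = as.integer(n_genes),
                 n_pseudogenes = as.integer(n_pseudogenes),
                 lesion_spec = lesion_spec,
                 paralog_spacing_mean = paralog_spacing_mean,
                 paralog_spacing_sd = paralog_spacing_sd,
                 divergence = divergence,
                 signature_te = signature_te,
                 cluster_size = as.integer(cluster_size),
                 cluster_margin_bp = as.integer(cluster_margin_bp),
                 te_length_meanlog = te_length_meanlog,
                 te_length_sdlog = te_length_sdlog,
                 focal_pad_bp = as.integer(focal_pad_bp),
                 emit_sequence = isTRUE(emit_sequence)),
            class = "sim_config")
}

## --- gene family planting ---------------------------------------------------

# Codon-safe nucleotide divergence on a CDS (character scalar): substitutions
# are drawn per base; for protected sequences, any codon that becomes a stop
# has its mutated positions redrawn, and the start/stop codons are left
# untouched. Divergence on pseudogene templates uses the same rule so that
# the *planted* lesion is the only integrity-breaking change.
mutate_cds <- function(cds, divergence) {
  if (divergence <= 0) return(cds)
  chars <- strsplit(cds, "")[[1]]
  n <- length(chars)
  mask <- runif(n) < divergence
  mask[1:3] <- FALSE
  mask[(n - 2L):n] <- FALSE
  idx <- which(mask)
  bases <- c("A", "C", "G", "T")
  for (i in idx) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  codons_hit <- unique((idx - 1L) %/% 3L + 1L)
  for (cj in codons_hit) {
    rng <- (3L * cj - 2L):(3L * cj)
    tries <- 0L
    while (paste(chars[rng], collapse = "") %in% STOP_CODONS) {
      pos <- intersect(rng, idx)
      for (i in pos) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
      tries <- tries + 1L
      if (tries > 100L) stop("failed to avoid stop codon during divergence")
    }
  }
  paste(chars, collapse = "")
}

# Apply one lesion to a list of exon sequences (gene orientation); a deleted
# exon becomes NULL. Frameshift positions avoid the outer 12 bp of the exon
# so homology-based exon boundaries stay anchored.
apply_lesion <- function(exon_seqs, les, ref) {
  k <- les$exon_index
  if (k > length(ref$exon_seqs)) {
    stop("lesion exon_index ", k, " exceeds reference exon count")
  }
  if (is.null(exon_seqs[[k]])) stop("lesion targets an already-deleted exon")
  s <- exon_seqs[[k]]
  if (les$kind == "exon_deletion") {
    exon_seqs[k] <- list(NULL)
    return(exon_seqs)
  }
  if (les$kind == "frameshift_indel") {
    L <- nchar(s)
    pos <- sample(seq(13L, L - 12L), 1L)
    if (les$op == "del") {
      exon_seqs[[k]] <- paste0(substr(s, 1, pos - 1L),
                               substr(s, pos + les$length, L))
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), les$length, replace = TRUE),
                   collapse = "")
      exon_seqs[[k]] <- paste0(substr(s, 1, pos - 1L), ins,
                               substr(s, pos, L))
    }
    return(exon_seqs)
  }
  # nonsense substitution: exons are codon-aligned, so codon c occupies
  # bases (3c-2):(3c) of the exon
  ncod <- nchar(s) %/% 3L
  cj <- if (is.null(les$codon)) max(2L, ncod %/% 2L) else as.integer(les$codon)
  if (cj < 1L || cj > ncod) stop("nonsense codon index out of range")
  if (k == 1L && cj == 1L) stop("nonsense lesion cannot target the start codon")
  if (k == length(ref$exon_seqs) && cj == ncod) {
    stop("nonsense lesion cannot target the terminal stop codon")
  }
  substr(s, 3L * cj - 2L, 3L * cj) <- "TAA"
  exon_seqs[[k]] <- s
  exon_seqs
}

# Assemble a copy (gene orientation): kept exons joined by introns whose
# interiors are randomized but whose 10 bp boundary contexts are conserved.
assemble_copy <- function(exon_seqs, ref, gc) {
  keep <- which(!vapply(exon_seqs, is.null, logical(1)))
  parts <- character(0)
  rel_start <- integer(0); rel_end <- integer(0)
  pos <- 0L
  for (i in seq_along(keep)) {
    k <- keep[i]
    ex <- exon_seqs[[k]]
    parts <- c(parts, ex)
    rel_start <- c(rel_start, pos + 1L)
    pos <- pos + nchar(ex)
    rel_end <- c(rel_end, pos)
    if (i < length(keep)) {
      ilen <- ref$intron_lengths[k]
      interior <- random_dna(ilen - 20L, gc)
      intr <- paste0(ref$donor10, interior, ref$acceptor10)
      parts <- c(parts, intr)
      pos <- pos + nchar(intr)
    }
  }
  list(seq = paste(parts, collapse = ""), exon_index = keep,
       rel_start = rel_start, rel_end = rel_end, length = pos)
}

#' Plant a paralog family: mutated copies and their placements
#'
#' Generates `n_genes` intact and `n_pseudogenes` lesioned copies of the
#' reference gene (divergence applied codon-safely so "gene" labels stay
#' exact), arranges them into tandem clusters with Normal start-to-start
#' spacing, and assigns cluster positions on the contigs. This is the gene
#' half of [simulate_genome()], exposed for direct use.
#'
#' @param config A [sim_config()].
#' @param ref A [reference_gene()] model.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A list with `copies` (per-copy sequences and relative exon
#'   coordinates), `genes` (a `GRanges` with `gene_id`, `family`, `label`,
#'   `lesions` and an `exons` `GRangesList` column) and `seqinfo`.
#' @export
plant_gene_family <- function(config, ref = reference_gene(),
                              seed = config$seed) {
  with_seed(seed, plant_gene_family_impl(config, ref))
}

plant_gene_family_impl <- function(config, ref) {
  n <- config$n_genes + config$n_pseudogenes
  si <- Seqinfo(names(config$contig_lengths),
                as.integer(config$contig_lengths))
  if (n == 0L) {
    genes <- GRanges(seqinfo = si)
    mcols(genes)$gene_id <- character(0)
    return(list(copies = list(), genes = genes, seqinfo = si))
  }
  labels <- sample(c(rep("gene", config$n_genes),
                     rep("pseudogene", config$n_pseudogenes)))
  pseudo_slots <- which(labels == "pseudogene")
  copies <- vector("list", n)
  pj <- 0L
  for (i in seq_len(n)) {
    cds <- mutate_cds(ref$cds, config$divergence)
    ends <- cumsum(ref$exon_lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    exon_seqs <- as.list(substring(cds, starts, ends))
    lesions <- character(0)
    if (labels[i] == "pseudogene") {
      pj <- pj + 1L
      les <- config$lesion_spec[[pj]]
      exon_seqs <- apply_lesion(exon_seqs, les, ref)
      lesions <- les$kind
    }
    cp <- assemble_copy(exon_seqs, ref, config$gc_content)
    cp$label <- labels[i]
    cp$lesions <- lesions
    copies[[i]] <- cp
  }
  # clusters -> contigs (round-robin); within a contig clusters get equal
  # slots so they never collide
  cl_of <- (seq_len(n) - 1L) %/% config$cluster_size + 1L
  ncl <- max(cl_of)
  contig_of_cl <- (seq_len(ncl) - 1L) %% length(config$contig_lengths) + 1L
  margin <- config$cluster_margin_bp
  placements <- vector("list", n)
  for (cl in seq_len(ncl)) {
    members <- which(cl_of == cl)
    lens <- vapply(copies[members], `[[`, integer(1), "length")
    gaps <- numeric(length(members) - 1L)
    if (length(members) > 1L) {
      for (j in seq_len(length(members) - 1L)) {
        d <- rnorm(1, config$paralog_spacing_mean, config$paralog_spacing_sd)
        gaps[j] <- max(d, 1000, lens[j] + 100)
      }
    }
    extent <- if (length(members) > 1L) sum(gaps) + lens[length(members)]
              else lens[1]
    ci <- contig_of_cl[cl]
    L <- config$contig_lengths[ci]
    slots_here <- which(contig_of_cl == ci)
    slot_rank <- match(cl, slots_here)
    nslots <- length(slots_here)
    usable <- L - 2 * margin
    slot_len <- usable / nslots
    slot_lo <- margin + (slot_rank - 1) * slot_len
    play <- slot_len - extent
    if (play < 0) {
      stop("contig '", names(config$contig_lengths)[ci],
           "' too short to host the requested family cluster (needs ",
           round(extent + 2 * margin), " bp)")
    }
    start0 <- floor(slot_lo + runif(1) * play) + 1
    offs <- cumsum(c(0, gaps))
    for (j in seq_along(members)) {
      placements[[members[j]]] <- list(contig = names(config$contig_lengths)[ci],
                                       start = as.integer(start0 + offs[j]),
                                       cluster = cl)
    }
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gene_gr <- GRanges(
    vapply(placements, `[[`, character(1), "contig"),
    IRanges(start = vapply(placements, `[[`, integer(1), "start"),
            width = vapply(copies, `[[`, integer(1), "length")),
    strand = strands, seqinfo = si)
  ids <- sprintf("fam%03d", seq_len(n))
  mcols(gene_gr)$gene_id <- ids
  mcols(gene_gr)$family <- "focal"
  mcols(gene_gr)$label <- labels
  mcols(gene_gr)$lesions <- vapply(copies, function(cp)
    paste(cp$lesions, collapse = ","), character(1))
  mcols(gene_gr)$cluster <- vapply(placements, `[[`, numeric(1), "cluster")
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- copies[[i]]
    gs <- start(gene_gr)[i]; glen <- cp$length
    if (strands[i] == "+") {
      es <- gs + cp$rel_start - 1L
      ee <- gs + cp$rel_end - 1L
    } else {
      es <- gs + glen - cp$rel_end
      ee <- gs + glen - cp$rel_start
    }
    o <- order(es)
    exg <- GRanges(seqnames(gene_gr)[i], IRanges(es[o], ee[o]), seqinfo = si)
    mcols(exg)$exon_rank <- cp$exon_index[o]
    exon_list[[i]] <- exg
  }
  mcols(gene_gr)$exons <- as(exon_list, "GRangesList")
  names(gene_gr) <- ids
  list(copies = copies, genes = gene_gr, seqinfo = si)
}

## --- TE planting ------------------------------------------------------------

#' Plant a TE landscape around (and away from) focal loci
#'
#' Places TE annotations as a stationary Boolean model: element starts follow
#' a Poisson process whose rate is chosen so the realized merged coverage
#' matches `background_te_density` outside focal windows and
#' `min(1, factor * density)` inside them, with log-normal element lengths
#' and family labels drawn from `te_family_mix`. When the config carries a
#' [signature_te()] rule, one signature element is additionally planted per
#' focal locus at a fixed offset from the last exon, antisense to the gene
#' with the stated probability.
#'
#' Elements are annotation intervals only: the genome sequence is not
#' modified (TE discovery is out of scope; all downstream statistics consume
#' intervals).
#'
#' @param genes Focal gene `GRanges` (as from [plant_gene_family()]); may be
#'   empty.
#' @param contigs Contig lengths (see [expand_to_window()]).
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to `config$seed + 1` stream).
#' @return A `GRanges` with metadata `family`, `element_id`, `signature`.
#' @export
plant_tes <- function(genes, contigs, config, seed = child_seed(config$seed, 1)) {
  with_seed(seed, plant_tes_impl(genes, contigs, config))
}

plant_tes_impl <- function(genes, contigs, config) {
  si <- as_contigs(contigs)
  mean_len <- exp(config$te_length_meanlog + config$te_length_sdlog^2 / 2)
  c_bg <- config$background_te_density
  c_f <- min(0.999, config$focal_enrichment_factor * c_bg)
  rho_bg <- if (c_bg > 0) -log(1 - c_bg) / mean_len else 0
  rho_f <- if (c_f > 0) -log(1 - c_f) / mean_len else 0
  genome_gr <- GRanges(seqnames(si), IRanges(1L, seqlengths(si)), seqinfo = si)
  if (length(genes)) {
    focal <- reduce(granges(expand_to_window(
      genes, window_spec("gene_span_pad", pad_bp = config$focal_pad_bp), si)),
      ignore.strand = TRUE)
  } else {
    focal <- GRanges(seqinfo = si)
  }
  background <- setdiff(genome_gr, focal, ignore.strand = TRUE)
  sample_segment_tes <- function(segments, rho) {
    if (rho <= 0 || !length(segments)) return(GRanges(seqinfo = si))
    nper <- rpois(length(segments), rho * width(segments))
    tot <- sum(nper)
    if (tot == 0L) return(GRanges(seqinfo = si))
    seg_i <- rep(seq_along(segments), nper)
    starts <- start(segments)[seg_i] +
      floor(runif(tot) * width(segments)[seg_i])
    lens <- pmax(50, round(rlnorm(tot, config$te_length_meanlog,
                                  config$te_length_sdlog)))
    chr <- as.character(seqnames(segments))[seg_i]
    ends <- pmin(starts + lens - 1, seqlengths(si)[chr])
    GRanges(chr, IRanges(as.integer(starts), as.integer(ends)),
            strand = sample(c("+", "-"), tot, replace = TRUE), seqinfo = si)
  }
  tes <- c(sample_segment_tes(background, rho_bg),
           sample_segment_tes(focal, rho_f))
  if (length(tes)) {
    mcols(tes)$family <- sample(names(config$te_family_mix), length(tes),
                                replace = TRUE, prob = config$te_family_mix)
    mcols(tes)$signature <- FALSE
  } else {
    mcols(tes)$family <- character(0)
    mcols(tes)$signature <- logical(0)
  }
  sig <- config$signature_te
  if (!is.null(sig) && length(genes)) {
    ex <- mcols(genes)$exons
    sig_gr <- GRanges(seqinfo = si)
    for (i in seq_along(genes)) {
      exg <- ex[[i]]
      gstrand <- as.character(strand(genes))[i]
      last_ex <- exg[which.max(mcols(exg)$exon_rank)]
      chr <- as.character(seqnames(genes))[i]
      if (gstrand == "-") {
        e <- start(last_ex) - sig$offset_bp
        s <- e - sig$length_bp + 1L
      } else {
        s <- end(last_ex) + sig$offset_bp
        e <- s + sig$length_bp - 1L
      }
      s <- max(1L, as.integer(s)); e <- min(seqlengths(si)[chr], as.integer(e))
      anti <- runif(1) < sig$antisense_prob
      st <- if (anti) setdiff(c("+", "-"), gstrand) else gstrand
      g <- GRanges(chr, IRanges(s, e), strand = st, seqinfo = si)
      mcols(g)$family <- sig$family
      mcols(g)$signature <- TRUE
      sig_gr <- c(sig_gr, g)
    }
    tes <- c(tes, sig_gr)
  }
  tes <- sort(tes, ignore.strand = TRUE)
  if (length(tes)) {
    mcols(tes)$element_id <- sprintf("te_%06d", seq_along(tes))
  } else {
    mcols(tes)$element_id <- character(0)
  }
  tes
}

## --- full genome simulation -------------------------------------------------

#' Simulate a genome with planted family loci and TE landscape
#'
#' End-to-end generator: plants the paralog family ([plant_gene_family()]),
#' emits the genome sequence with the copies spliced in (background is
#' i.i.d. nucleotides at the configured GC), plants the TE landscape
#' ([plant_tes()]), and records a truth table. Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `family_sim` list: `seqinfo`, `genome` (`DNAStringSet`, or
#'   `NULL` when `emit_sequence = FALSE`), `genes` (`GRanges` with `exons`
#'   column), `tes` (`GRanges`), `proteins` (`AAStringSet` of conceptual
#'   translations), `truth` (data.frame) and `config`.
#' @examples
#' cfg <- sim_config(seed = 7, contig_lengths = c(c1 = 4e5),
#'                   n_genes = 2, n_pseudogenes = 1, cluster_size = 3,
#'                   cluster_margin_bp = 5e4, background_te_density = 0.2)
#' sim <- simulate_genome(cfg)
#' sim$truth[, c("locus_id", "label", "lesions")]
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- reference_gene()
  with_seed(config$seed, {
    fam <- plant_gene_family_impl(config, ref)
    genes <- fam$genes
    si <- fam$seqinfo
    genome <- NULL
    if (config$emit_sequence) {
      seqs <- vapply(seqlengths(si), function(L)
        random_dna(L, config$gc_content), character(1))
      genome <- DNAStringSet(seqs)
      names(genome) <- seqlevels(si)
      if (length(genes)) {
        for (i in seq_along(genes)) {
          chr <- as.character(seqnames(genes))[i]
          cp_seq <- fam$copies[[i]]$seq
          if (as.character(strand(genes))[i] == "-") {
            cp_seq <- as.character(reverseComplement(DNAString(cp_seq)))
          }
          genome[[chr]] <- Biostrings::replaceAt(
            genome[[chr]],
            IRanges(start(genes)[i], end(genes)[i]),
            DNAString(cp_seq))
        }
      }
    }
    tes <- plant_tes_impl(genes, si, config)
    spliced <- vapply(fam$copies, function(cp)
      paste(unlist(lapply(seq_along(cp$exon_index), function(j)
        substr(cp$seq, cp$rel_start[j], cp$rel_end[j]))), collapse = ""),
      character(1))
    ntr <- 3L * (nchar(spliced) %/% 3L)
    prot <- suppressWarnings(
      translate(DNAStringSet(substr(spliced, 1, ntr)), if.fuzzy.codon = "X"))
    names(prot) <- if (length(genes)) genes$gene_id else character(0)
    truth <- data.frame(
      locus_id = if (length(genes)) genes$gene_id else character(0),
      contig = as.character(seqnames(genes)),
      start = start(genes), end = end(genes),
      strand = as.character(strand(genes)),
      label = if (length(genes)) genes$label else character(0),
      lesions = if (length(genes)) genes$lesions else character(0),
      cluster = if (length(genes)) genes$cluster else numeric(0))
    structure(list(seqinfo = si, genome = genome, genes = genes, tes = tes,
                   proteins = prot, truth = truth, config = config),
              class = "family_sim")
  })
}

#' @export
print.family_sim <- function(x, ...) {
  cat("family_sim:", length(seqlengths(x$seqinfo)), "contig(s),",
      sum(as.double(seqlengths(x$seqinfo))), "bp;",
      length(x$genes), "family loci (",
      sum(x$truth$label == "gene"), "genes /",
      sum(x$truth$label == "pseudogene"), "pseudogenes );",
      length(x$tes), "TEs\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa` (when sequence was generated), `genes.gff3`, `tes.bed`,
#' `proteins.fa`, `truth.tsv` and `truth.json` under `dir`.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$genome)) {
    writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  }
  if (length(sim$genes)) {
    write_gene_models_gff3(sim$genes, file.path(dir, "genes.gff3"))
  }
  write_te_bed(sim$tes, file.path(dir, "tes.bed"))
  if (length(sim$proteins)) {
    writeXStringSet(sim$proteins, file.path(dir, "proteins.fa"))
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
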