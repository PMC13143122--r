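## Motif representation: a motif is an ordered list of column classes, each a
## character vector of allowed residues, or NULL for a wildcard column.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Define a protein motif as per-column residue classes
#'
#' @param name Motif name (e.g. `"FARM"`, `"IGM3"`).
#' @param columns A list with one element per motif column: a character vector
#'   of allowed residues, or `NULL` for a wildcard column. Alternatively a
#'   single pattern string such as `"DDxxD"` (`x` = wildcard, `[DE]` = class).
#' @param source `"built_in"` or `"trained"`.
#' @return A `motif_definition` object.
#' @examples
#' motif_definition("FARM", "DDxxD")
#' @export
motif_definition <- function(name, columns, source = "built_in") {
  if (is.character(columns) && length(columns) == 1L) {
    columns <- parse_motif_pattern(columns)
  }
  stopifnot(is.list(columns), length(columns) >= 3L)
  for (cl in columns) {
    if (is.null(cl)) next
    if (!all(cl %in% AA20)) {
      stop("motif column contains non-standard residue(s): ",
           paste(setdiff(cl, AA20), collapse = ","))
    }
  }
  structure(list(name = name, columns = columns, source = source),
            class = "motif_definition")
}

# "DDxxD" / "K[TS]xQ" -> list of column classes
parse_motif_pattern <- function(pattern) {
  out <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x" || ch == ".") {
      out[length(out) + 1L] <- list(NULL) # wildcard column
      i <- i + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unclosed [ in motif pattern")
      out[[length(out) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

#' @export
print.motif_definition <- function(x, ...) {
  cat("motif", x$name, "(", x$source, "):",
      motif_consensus_string(x), "\n")
  invisible(x)
}

# Human-readable pattern: single residues as-is, classes bracketed, wildcard x.
motif_consensus_string <- function(motif) {
  paste(vapply(motif$columns, function(cl) {
    if (is.null(cl)) "x"
    else if (length(cl) == 1L) cl
    else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Consensus sequence used when constructing synthetic proteins: first allowed
# residue per column, 'A' at wildcards.
motif_consensus_seq <- function(motif) {
  paste(vapply(motif$columns, function(cl) if (is.null(cl)) "A" else cl[1],
               character(1)), collapse = "")
}

#' Built-in motif set
#'
#' The aspartate-rich motifs FARM and SARM are defined by their canonical
#' `DDxxD` consensus. The six insect-GGPPS motifs (IGM1-IGM6) are *synthetic
#' placeholder* definitions: the real IGM column boundaries come from an
#' external alignment convention and should be supplied as trained
#' definitions ([build_motif_regex()]) for real analyses; the placeholders
#' exist so that the classifier, the synthetic protein panel and the pipeline
#' are runnable out of the box. IGM4 carries the conserved KT dipeptide of
#' the canonical insect GGPPS active site.
#'
#' @return A named list of [motif_definition()] objects:
#'   FARM, SARM, IGM1..IGM6.
#' @export
built_in_motifs <- function() {
  defs <- list(
    FARM = "DDxxD",
    SARM = "DDxxD",
    IGM1 = "QIxEL",
    IGM2 = "RGxPF",
    IGM3 = "GQxxDL",
    IGM4 = "KTxxLE",
    IGM5 = "FQxxDY",
    IGM6 = "RYxSxV"
  )
  Map(function(nm, pat) motif_definition(nm, pat, source = "built_in"),
      names(defs), defs)
}

#' Scan a protein for a motif
#'
#' Reports every position (left to right) where the protein matches the
#' motif's column classes. `X` residues in the protein match only wildcard
#' columns.
#'
#' @param protein A character string or `AAString`.
#' @param motif A [motif_definition()].
#' @return A data.frame with columns `motif_name`, `start` (1-based),
#'   `match` (the matched span) and `exact` (TRUE when every column is a
#'   single-residue class matched literally). Zero rows when no match.
#' @examples
#' scan_motif("AAADDYLDAAA", motif_definition("FARM", "DDxxD"))
#' @export
scan_motif <- function(protein, motif) {
  stopifnot(inherits(motif, "motif_definition"))
  p <- as.character(protein)
  chars <- strsplit(p, "")[[1]]
  L <- length(chars)
  k <- length(motif$columns)
  empty <- data.frame(motif_name = character(), start = integer(),
                      match = character(), exact = logical())
  if (L < k) return(empty)
  ok <- rep(TRUE, L - k + 1L)
  for (j in seq_len(k)) {
    cl <- motif$columns[[j]]
    if (is.null(cl)) next
    ok <- ok & chars[seq_len(L - k + 1L) + j - 1L] %in% cl
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  fixed <- all(lengths(motif$columns) == 1L) &&
    !any(vapply(motif$columns, is.null, logical(1)))
  data.frame(motif_name = motif$name, start = starts,
             match = vapply(starts, function(s)
               paste(chars[s:(s + k - 1L)], collapse = ""), character(1)),
             exact = fixed)
}

#' Assign FARM and SARM among DDxxD hits
#'
#' Canonical isoprenyl diphosphate synthases carry two aspartate-rich DDxxD
#' motifs. By the package's declared convention the first DDxxD hit is the
#' FARM; the SARM is the next hit starting at least `min_separation` residues
#' downstream of the FARM start (default 80, reflecting the helix bundle
#' between the two motifs).
#'
#' @param protein Protein sequence (character or `AAString`).
#' @param motif DDxxD-class [motif_definition()] (default the built-in FARM).
#' @param min_separation Minimum SARM-FARM start separation, residues.
#' @return A list with `farm_start` and `sarm_start` (1-based positions or
#'   `NA`), and `hits` (all DDxxD-class hits).
#' @export
assign_farm_sarm <- function(protein, motif = built_in_motifs()$FARM,
                             min_separation = 80L) {
  hits <- scan_motif(protein, motif)
  farm <- if (nrow(hits)) hits$start[1] else NA_integer_
  sarm <- NA_integer_
  if (!is.na(farm)) {
    cand <- hits$start[hits$start >= farm + min_separation]
    if (length(cand)) sarm <- cand[1]
  }
  list(farm_start = farm, sarm_start = sarm, hits = hits)
}

#' Classify an IDS protein as canonical or divergent
#'
#' Applies the family-level motif logic: a protein with FARM, SARM and all
#' six IGMs is `canonical`; one retaining FARM and IGM3 but lacking at least
#' one other IGM is `divergent_like` (the conservation pattern characteristic
#' of the divergent GGPPS-like clade); anything else is `indeterminate`. The
#' full per-motif status map is returned so callers can apply other rules.
#'
#' @param protein Protein sequence (character or `AAString`).
#' @param motifs Named list of [motif_definition()]s containing `FARM`,
#'   `SARM` and `IGM1`..`IGM6` (default [built_in_motifs()]).
#' @param min_separation FARM/SARM separation rule, see [assign_farm_sarm()].
#' @return A `family_call` list: `id`-free status map (`status`, named
#'   logical), `call`, `length_ok` (>= 150 aa), `farm_start`, `sarm_start`.
#' @export
classify_ids_family <- function(protein, motifs = built_in_motifs(),
                                min_separation = 80L) {
  need <- c("FARM", "SARM", paste0("IGM", 1:6))
  missing_defs <- setdiff(need, names(motifs))
  if (length(missing_defs)) {
    stop("motif set lacks definition(s): ", paste(missing_defs, collapse = ","))
  }
  p <- as.character(protein)
  fs <- assign_farm_sarm(p, motifs$FARM, min_separation)
  status <- c(FARM = !is.na(fs$farm_start), SARM = !is.na(fs$sarm_start))
  for (ig in paste0("IGM", 1:6)) {
    status[[ig]] <- nrow(scan_motif(p, motifs[[ig]])) > 0L
  }
  igms <- status[paste0("IGM", 1:6)]
  call <- if (status[["FARM"]] && status[["SARM"]] && all(igms)) {
    "canonical"
  } else if (status[["FARM"]] && status[["IGM3"]] &&
             any(!igms[setdiff(names(igms), "IGM3")])) {
    "divergent_like"
  } else {
    "indeterminate"
  }
  structure(list(status = status, call = call,
                 length_ok = nchar(p) >= 150L,
                 farm_start = fs$farm_start, sarm_start = fs$sarm_start),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat("IDS family call:", x$call, "\n  motifs:",
      paste(names(x$status)[x$status], collapse = " "), "\n")
  invisible(x)
}

#' Classify a set of proteins
#'
#' Vectorised wrapper around [classify_ids_family()].
#'
#' @param proteins An `AAStringSet` or named character vector.
#' @param motifs,min_separation See [classify_ids_family()].
#' @return A data.frame with one row per protein: `id`, `length`,
#'   `length_ok`, one logical column per motif, and `call`.
#' @export
classify_proteins <- function(proteins, motifs = built_in_motifs(),
                              min_separation = 80L) {
  seqs <- as.character(proteins)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    fc <- classify_ids_family(seqs[[i]], motifs, min_separation)
    c(list(id = ids[i], length = nchar(seqs[[i]]), length_ok = fc$length_ok),
      as.list(fc$status), list(call = fc$call))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Select sequences for phylogenetic analysis
#'
#' Keeps exactly the proteins at least 150 residues long that contain both a
#' FARM and a SARM hit (per [assign_farm_sarm()]), the standard inclusion
#' rule for IDS phylogenies.
#'
#' @param proteins `AAStringSet` or named character vector.
#' @param min_length Minimum length in residues (default 150).
#' @param motif DDxxD-class motif used for FARM/SARM detection.
#' @param min_separation See [assign_farm_sarm()].
#' @return The qualifying subset, same class as the input.
#' @export
filter_phylogeny_set <- function(proteins, min_length = 150L,
                                 motif = built_in_motifs()$FARM,
                                 min_separation = 80L) {
  seqs <- as.character(proteins)
  keep <- vapply(seqs, function(s) {
    if (nchar(s) < min_length) return(FALSE)
    fs <- assign_farm_sarm(s, motif, min_separation)
    !is.na(fs$farm_start) && !is.na(fs$sarm_start)
  }, logical(1))
  proteins[keep]
}

#' Train a motif definition from an alignment
#'
#' Builds per-column residue classes from an alignment slice: for every
#' column in `boundaries`, the allowed set is the residues whose frequency
#' among non-gap characters is at least `min_residue_freq`. A column whose
#' allowed set equals all residues observed there and spans at least 15
#' residues becomes a wildcard. Columns where gaps are the majority are
#' rejected (a motif cannot sit in an indel-riddled region).
#'
#' @param alignment Aligned sequences of equal length: `AAStringSet` or
#'   character vector (gaps as `-`).
#' @param boundaries Integer vector of alignment columns (e.g. `12:16`)
#'   delimiting the motif.
#' @param name Motif name for the resulting definition.
#' @param min_residue_freq Minimum within-column frequency for a residue to
#'   enter the allowed set (default 0.05).
#' @return A `trained` [motif_definition()].
#' @export
build_motif_regex <- function(alignment, boundaries, name = "motif",
                              min_residue_freq = 0.05) {
  seqs <- as.character(alignment)
  if (length(seqs) < 5L) stop("need at least 5 training sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("training sequences are not aligned (unequal length)")
  boundaries <- as.integer(boundaries)
  if (any(boundaries < 1L | boundaries > L)) {
    stop("motif boundaries outside alignment width ", L)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  cols <- lapply(boundaries, function(j) {
    col <- mat[, j]
    gaps <- col %in% c("-", ".")
    if (mean(gaps) > 0.5) {
      stop("gap-majority alignment column ", j, " inside motif boundaries")
    }
    col <- col[!gaps]
    freq <- table(col) / length(col)
    allowed <- names(freq)[freq >= min_residue_freq]
    observed <- names(freq)
    if (setequal(allowed, observed) && length(allowed) >= 15L) {
      NULL
    } else {
      sort(allowed)
    }
  })
  motif_definition(name, cols, source = "trained")
}

#' Position frequency matrix and information content of motif instances
#'
#' @param instances Equal-length, ungapped motif instances (`AAStringSet` or
#'   character vector).
#' @return A `logo_matrix` list: `freq`, a 20 x L matrix of per-column
#'   residue frequencies (columns sum to 1), and `ic`, per-column information
#'   content in bits (`log2(20)` minus the Shannon entropy of the column).
#' @examples
#' lm <- logo_matrix(c("DDYLD", "DDFID", "DDYID"))
#' lm$ic
#' @export
logo_matrix <- function(instances) {
  seqs <- as.character(instances)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("motif instances have unequal lengths")
  mat <- do.call(rbind, strsplit(seqs, ""))
  if (any(mat %in% c("-", "."))) stop("motif instances must be ungapped")
  freq <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = AA20))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- AA20
  ic <- apply(freq, 2, function(f) {
    nz <- f[f > 0]
    log2(20) - (-sum(nz * log2(nz)))
  })
  structure(list(freq = freq, ic = ic), class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("logo_matrix:", ncol(x$freq), "columns; IC (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Write / read motif definitions as JSON
#'
#' @param motifs Named list of [motif_definition()]s.
#' @param file Path.
#' @return `file` invisibly; `read_motifs_json()` returns the motif list.
#' @export
write_motifs_json <- function(motifs, file) {
  obj <- lapply(motifs, function(m) {
    list(name = m$name, source = m$source,
         columns = lapply(m$columns, function(cl)
           if (is.null(cl)) "" else paste(cl, collapse = "")))
  })
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_motifs_json
#' @export
read_motifs_json <- function(file) {
  obj <- jsonlite::read_json(file)
  out <- lapply(obj, function(m) {
    cols <- lapply(m$columns, function(s)
      if (identical(s, "") || is.null(s)) NULL else strsplit(s, "")[[1]])
    motif_definition(m$name, cols, source = m$source)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
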