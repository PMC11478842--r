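#' Construct a plastome record
#'
#' The central container for one circular plastome: its sequence (linearized at
#' the stored origin), accession, species and feature annotations. Coordinates
#' throughout the package are 1-based closed intervals on the linearized
#' sequence, the R/Bioconductor convention.
#'
#' @param accession nonempty accession identifier
#' @param species species name
#' @param sequence DNA string over {A,C,G,T,N}; coerced to uppercase
#' @param features list of [gene_feature()] objects
#' @return an object of class `plastome_record` with fields `accession`,
#'   `species`, `sequence`, `features`, `length`
#' @export
plastome_record <- function(accession, species, sequence, features = list()) {
  if (!nzchar(accession)) stop("accession must be nonempty")
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  bad <- setdiff(unique(seq_chars(sequence)), c(DNA_BASES, "N"))
  if (length(bad)) stop("sequence contains non-DNA characters: ", paste(bad, collapse = ","))
  structure(
    list(accession = accession, species = species, sequence = sequence,
         features = features, length = nchar(sequence)),
    class = "plastome_record"
  )
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s): %s bp, %d features\n",
              x$accession, x$species, format(x$length, big.mark = ","),
              length(x$features)))
  invisible(x)
}

#' Construct a gene feature
#'
#' One located copy of a gene. IR-duplicated genes are distinct features
#' sharing a name; a feature that wraps the linearization origin is split into
#' two parts and carries `wraps = TRUE`.
#'
#' @param name gene symbol
#' @param kind one of "CDS", "tRNA", "rRNA", "pseudogene"
#' @param strand "+" or "-"
#' @param parts integer matrix with columns `start`, `end` (1-based closed),
#'   ordered, non-overlapping; gaps between parts are introns
#' @param wraps TRUE when the feature crosses the linearization origin (its
#'   two parts are then the origin-split halves, not an intron)
#' @return an object of class `gene_feature`
#' @export
gene_feature <- function(name, kind, strand, parts, wraps = FALSE) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "pseudogene"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  parts <- matrix(as.integer(parts), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(parts[, "end"] < parts[, "start"]))
    stop("feature part with end < start: ", name)
  if (nrow(parts) > 1L && !wraps) {
    o <- order(parts[, "start"])
    parts <- parts[o, , drop = FALSE]
    if (any(parts[-1L, "start"] <= parts[-nrow(parts), "end"]))
      stop("overlapping parts within feature ", name)
  }
  structure(
    list(name = name, kind = kind, strand = strand, parts = parts,
         intron_count = if (wraps) 0L else nrow(parts) - 1L, wraps = wraps),
    class = "gene_feature"
  )
}

#' Total span of a feature in bases (sum of part lengths)
#' @param feature a [gene_feature()]
#' @return integer length
#' @export
feature_length <- function(feature) {
  sum(feature$parts[, "end"] - feature$parts[, "start"] + 1L)
}

#' Extract the (strand-oriented) sequence of a feature
#'
#' Parts are concatenated in order and reverse-complemented for minus-strand
#' features, yielding the coding-strand sequence for a CDS.
#'
#' @param record a [plastome_record()]
#' @param feature a [gene_feature()] of that record
#' @return DNA string
#' @export
feature_sequence <- function(record, feature) {
  pieces <- apply(feature$parts, 1L, function(p) substr(record$sequence, p[1L], p[2L]))
  s <- paste(pieces, collapse = "")
  if (feature$strand == "-") revcomp(s) else s
}

#' Rotate a plastome record so a given position becomes position 1
#'
#' Used to canonicalize linearization so that the LSC starts at position 1.
#' Feature coordinates are rotated along; features that come to span the new
#' origin are split and flagged.
#'
#' @param record a [plastome_record()]
#' @param new_start 1-based position in the current linearization
#' @return the rotated `plastome_record`
#' @export
rotate_record <- function(record, new_start) {
  n <- record$length
  if (new_start == 1L) return(record)
  s <- record$sequence
  rotated <- paste0(substr(s, new_start, n), substr(s, 1L, new_start - 1L))
  shift <- function(p) ((p - new_start) %% n) + 1L
  feats <- lapply(record$features, function(f) {
    parts <- f$parts
    parts[, "start"] <- shift(parts[, "start"])
    parts[, "end"] <- shift(parts[, "end"])
    wraps <- f$wraps
    if (any(parts[, "end"] < parts[, "start"])) {
      # feature now crosses the new origin: split the offending part
      i <- which(parts[, "end"] < parts[, "start"])[1L]
      parts <- rbind(
        cbind(start = parts[i, "start"], end = n),
        cbind(start = 1L, end = parts[i, "end"])
      )
      wraps <- TRUE
    }
    gene_feature(f$name, f$kind, f$strand, parts, wraps = wraps)
  })
  plastome_record(record$accession, record$species, rotated, feats)
}
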