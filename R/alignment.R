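# Gapped multi-accession alignment with species labels and a designated
# reference row. Stored as a character matrix (rows = accessions) for fast
# column-wise operations; FASTA I/O goes through Biostrings.

#' Construct an alignment matrix
#'
#' @param mat character matrix of single characters over {A,C,G,T,N,-};
#'   rownames are accessions
#' @param species named character vector mapping accession to species; must
#'   cover every row
#' @param reference_id accession of the reference row (coordinates of SNP and
#'   indel calls are expressed on its ungapped sequence)
#' @return an object of class `plast_alignment` with fields `matrix`,
#'   `species`, `reference_id`, `column_map` (alignment column to reference
#'   position, NA at reference gaps) and `ref_column` (reference position to
#'   alignment column)
#' @export
plast_alignment <- function(mat, species, reference_id) {
  if (is.null(rownames(mat))) stop("alignment matrix must have accession rownames")
  missing <- setdiff(rownames(mat), names(species))
  if (length(missing))
    stop("accession(s) missing from the species map: ", paste(missing, collapse = ", "))
  if (!reference_id %in% rownames(mat))
    stop("reference accession not present in the alignment: ", reference_id)
  mat[] <- toupper(mat)
  ref_bases <- mat[reference_id, ] != "-"
  column_map <- ifelse(ref_bases, cumsum(ref_bases), NA_integer_)
  structure(
    list(matrix = mat,
         species = species[rownames(mat)],
         reference_id = reference_id,
         column_map = as.integer(column_map),
         ref_column = which(ref_bases)),
    class = "plast_alignment"
  )
}

#' @export
print.plast_alignment <- function(x, ...) {
  cat(sprintf("<plast_alignment> %d accessions x %s columns (reference %s)\n",
              nrow(x$matrix), format(ncol(x$matrix), big.mark = ","), x$reference_id))
  invisible(x)
}

#' Number of accessions / columns of an alignment
#' @param aln a [plast_alignment()]
#' @return integer
#' @export
n_accessions <- function(aln) nrow(aln$matrix)

#' @rdname n_accessions
#' @export
n_columns <- function(aln) ncol(aln$matrix)

#' Accessions belonging to a species
#' @param aln a [plast_alignment()]
#' @param species species name
#' @return character vector of accessions
#' @export
accessions_of <- function(aln, species) {
  names(aln$species)[aln$species == species]
}

#' Read an aligned FASTA plus a species map into an alignment matrix
#'
#' @param fasta_path aligned FASTA (all rows equal length; gaps as `-`)
#' @param species_tsv TSV with header columns `accession` and `species`
#'   mapping every alignment row
#' @param reference_id accession of the reference row
#' @return a [plast_alignment()]
#' @export
read_alignment <- function(fasta_path, species_tsv, reference_id) {
  set <- Biostrings::readBStringSet(fasta_path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) > 1L)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(as.character(set)), "", fixed = TRUE))
  rownames(mat) <- sub("\\s.*$", "", names(set))
  map <- utils::read.delim(species_tsv, stringsAsFactors = FALSE)
  if (!all(c("accession", "species") %in% names(map)))
    stop("species map must have 'accession' and 'species' columns")
  species <- stats::setNames(map$species, map$accession)
  plast_alignment(mat, species, reference_id)
}

#' Write an alignment and its species map back to disk
#'
#' Inverse of [read_alignment()]; round-trips bit-identically.
#'
#' @param aln a [plast_alignment()]
#' @param fasta_path output aligned FASTA path
#' @param species_tsv optional output TSV path for the species map
#' @return `fasta_path`, invisibly
#' @export
write_alignment <- function(aln, fasta_path, species_tsv = NULL) {
  rows <- apply(aln$matrix, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(rows)
  names(set) <- rownames(aln$matrix)
  Biostrings::writeXStringSet(set, fasta_path, width = 80L)
  if (!is.null(species_tsv)) {
    utils::write.table(
      data.frame(accession = names(aln$species), species = unname(aln$species)),
      species_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Ungapped sequence of one alignment row
#' @param aln a [plast_alignment()]
#' @param accession row to extract
#' @return DNA string without gaps
#' @export
ungapped_sequence <- function(aln, accession) {
  row <- aln$matrix[accession, ]
  chars_seq(row[row != "-"])
}

# Map alignment columns to ungapped coordinates of an arbitrary row
# (NA where that row is gapped).
#' @keywords internal
row_position_map <- function(aln, accession) {
  bases <- aln$matrix[accession, ] != "-"
  ifelse(bases, cumsum(bases), NA_integer_)
}

# All unordered row pairs of an alignment (2 x n matrix of accession names).
#' @keywords internal
accession_pairs <- function(aln, subset = NULL) {
  acc <- if (is.null(subset)) rownames(aln$matrix) else subset
  if (length(acc) < 2L) return(matrix(character(0), nrow = 2L))
  utils::combn(acc, 2L)
}
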