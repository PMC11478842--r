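`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Split a sequence string into a character vector of single bases
#' @keywords internal
seq_chars <- function(x) {
  if (length(x) != 1L) stop("expected a single string")
  strsplit(x, "", fixed = TRUE)[[1]]
}

#' @keywords internal
chars_seq <- function(x) paste(x, collapse = "")

#' Reverse a string without splitting
#' @keywords internal
reverse_str <- function(x) intToUtf8(rev(utf8ToInt(x)))

#' Reverse complement of a DNA string
#'
#' Fast string-level reverse complement over the {A,C,G,T,N,-} alphabet.
#' @param x single DNA string (uppercase)
#' @return the reverse-complemented string
#' @export
revcomp <- function(x) reverse_str(chartr("ACGTN", "TGCAN", x))

#' @keywords internal
complement_chars <- function(x) unname(.COMPLEMENT[x])

#' @keywords internal
revcomp_chars <- function(x) rev(complement_chars(x))

#' GC fraction of a base vector, Ns excluded from the denominator
#' @keywords internal
gc_fraction <- function(chars) {
  acgt <- sum(chars == "A") + sum(chars == "C") + sum(chars == "G") + sum(chars == "T")
  if (acgt == 0L) return(NA_real_)
  (sum(chars == "G") + sum(chars == "C")) / acgt
}

#' @keywords internal
is_base <- function(x) x == "A" | x == "C" | x == "G" | x == "T"

#' @keywords internal
plast_warning <- function(msg) {
  warning(warningCondition(msg, class = "plastomarker_warning"))
}

# Extract [start,end] runs of TRUE from a logical vector (1-based inclusive).
#' @keywords internal
true_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Circular interval length on a genome of size n; start > end means the
# interval wraps the origin.
#' @keywords internal
circ_length <- function(start, end, n) {
  ifelse(start <= end, end - start + 1L, n - start + 1L + end)
}
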