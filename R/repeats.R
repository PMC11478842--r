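# Repeat cataloguing under field-standard thresholds: perfect microsatellites
# (MISA-like unit/copy thresholds), dispersed repeats of the four REPuter
# orientations (forward, palindromic, reverse, complementary) by
# seed-and-extend with a mismatch budget, and approximate tandem arrays by
# period-wise self-comparison.

.SSR_THRESHOLDS <- c(`1` = 7L, `2` = 4L, `3` = 3L, `4` = 3L, `5` = 3L, `6` = 3L)

# lexicographically minimal rotation of a motif
#' @keywords internal
canonical_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L)), "")
  min(rots)
}

# smallest shift q < nchar(motif) at which the motif agrees with itself over
# the overlap (weak period); nchar(motif) when none
#' @keywords internal
.weak_period <- function(motif) {
  k <- nchar(motif)
  ch <- seq_chars(motif)
  for (q in seq_len(k - 1L)) {
    if (all(ch[seq_len(k - q)] == ch[seq.int(q + 1L, k)])) return(q)
  }
  k
}

# TRUE when motif is exactly periodic with some proper divisor period
#' @keywords internal
.motif_periodic <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(FALSE)
  ch <- seq_chars(motif)
  for (q in seq_len(k - 1L)) {
    if (k %% q == 0L && all(ch == rep_len(ch[seq_len(q)], k))) return(TRUE)
  }
  FALSE
}

#' Find perfect microsatellites (SSRs)
#'
#' Maximal perfect tandem runs of unit length 1-6 meeting the per-unit copy
#' thresholds (defaults: 7 copies for mononucleotides, 4 for dinucleotides, 3
#' for tri- to hexanucleotides). A run is reported at its smallest period: the
#' repeat unit must be aperiodic, so an A-run is never reported as an AA
#' dinucleotide repeat. Runs are truncated to whole copies from the run
#' start; Ns break runs. The reported `motif` is the lexicographically
#' minimal rotation of the unit (so TA runs report as "AT").
#'
#' @param sequence DNA string
#' @param thresholds named integer vector: minimum copies per unit length 1-6
#' @param circular scan across the origin by appending a wrap appendix
#'   (calls starting beyond the sequence end are deduplicated)
#' @return data.frame with columns motif (canonical), unit (as encountered),
#'   unit_len, copies, start, end (1-based closed; end may exceed the
#'   sequence length for origin-spanning calls on circular scans)
#' @export
find_ssrs <- function(sequence, thresholds = .SSR_THRESHOLDS, circular = FALSE) {
  n0 <- nchar(sequence)
  appendix <- 0L
  if (circular && n0 > 1L) {
    appendix <- min(n0 - 1L, max(thresholds * as.integer(names(thresholds))) * 2L)
    sequence <- paste0(sequence, substr(sequence, 1L, appendix))
  }
  s <- seq_chars(sequence)
  n <- length(s)
  rows <- list()
  for (p in as.integer(names(thresholds))) {
    if (n <= p) next
    thr <- thresholds[[as.character(p)]]
    eq <- s[seq_len(n - p)] == s[seq.int(p + 1L, n)] &
      is_base(s[seq_len(n - p)]) & is_base(s[seq.int(p + 1L, n)])
    runs <- true_runs(eq)
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      span_len <- runs[i, "end"] - runs[i, "start"] + 1L + p
      copies <- span_len %/% p
      if (copies < thr) next
      start <- runs[i, "start"]
      unit <- chars_seq(s[seq.int(start, start + p - 1L)])
      if (.motif_periodic(unit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = canonical_motif(unit), unit = unit, unit_len = p,
        copies = copies, start = start, end = start + copies * p - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), unit = character(0), unit_len = integer(0),
               copies = integer(0), start = integer(0), end = integer(0))
  if (appendix > 0L && nrow(out)) {
    # drop duplicates of calls already reported at start - n0
    out <- out[out$start <= n0, , drop = FALSE]
    key <- paste(((out$start - 1L) %% n0) + 1L, out$unit_len, out$copies)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find dispersed repeats (forward, palindromic, reverse, complementary)
#'
#' Reports maximal repeated segment pairs of length >= `min_len` with at most
#' `max_mismatch` mismatches, classed by orientation: F (direct copy), P
#' (reverse complement), R (reverse only), C (complement only). Maximality is
#' per alignment diagonal: a reported pair cannot be extended in either
#' direction without exceeding the mismatch budget, and its end positions
#' match exactly. Pairs fully nested inside a longer reported pair of the
#' same kind are suppressed; results are capped at `max_results` by
#' descending length.
#'
#' Detection is seed-and-extend: exact k-mer seeds shared between the
#' sequence and its transform select the diagonals that are then scanned
#' exhaustively. The default seed of 7 makes the scan exactly equivalent to a
#' brute-force all-pairs scan for `min_len` 30 / 3 mismatches; sequences over
#' 20 kb use seed 14 for speed (a missed repeat would need >= 30 bp with no
#' 14 bp exact stretch).
#'
#' @param sequence DNA string
#' @param min_len minimum repeat length (default 30)
#' @param max_mismatch mismatch budget per pair (default 3)
#' @param max_results cap on reported pairs (default 500)
#' @param kinds orientations to scan
#' @param seed_len exact seed length (NULL = automatic, see above)
#' @return data.frame with columns kind, start1, end1, start2, end2, length,
#'   mismatches
#' @export
find_dispersed_repeats <- function(sequence, min_len = 30L, max_mismatch = 3L,
                                   max_results = 500L,
                                   kinds = c("F", "P", "R", "C"),
                                   seed_len = NULL) {
  s <- seq_chars(toupper(sequence))
  n <- length(s)
  empty <- data.frame(kind = character(0), start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), mismatches = integer(0))
  if (n < min_len) return(empty)
  if (is.null(seed_len)) seed_len <- if (n > 20000L) 14L else 7L
  k <- min(seed_len, min_len)
  seq_str <- chars_seq(s)
  kmers_s <- substring(seq_str, seq_len(n - k + 1L), seq.int(k, n))
  valid <- !grepl("N", kmers_s, fixed = TRUE)

  out <- list()
  for (kind in kinds) {
    t_str <- switch(kind,
      F = seq_str,
      P = revcomp(seq_str),
      R = reverse_str(seq_str),
      C = chartr("ACGTN", "TGCAN", seq_str))
    t_chars <- seq_chars(t_str)
    kmers_t <- if (kind == "F") kmers_s else
      substring(t_str, seq_len(n - k + 1L), seq.int(k, n))
    valid_t <- !grepl("N", kmers_t, fixed = TRUE)
    idx_t <- split(which(valid_t), kmers_t[valid_t])
    idx_s <- split(which(valid), kmers_s[valid])
    common <- intersect(names(idx_s), names(idx_t))
    gs <- idx_s[common]
    gt <- idx_t[common]
    single <- lengths(gs) == 1L & lengths(gt) == 1L
    p1 <- unlist(gs[single], use.names = FALSE)
    q1 <- unlist(gt[single], use.names = FALSE)
    diags <- if (kind %in% c("F", "C")) {
      d <- q1 - p1
      d[d >= 1L]
    } else {
      p1 + n + 1L - q1
    }
    multi <- which(!single)
    acc <- vector("list", length(multi))
    for (w in seq_along(multi)) {
      ps <- gs[[multi[w]]]
      qs <- gt[[multi[w]]]
      if (kind %in% c("F", "C")) {
        d <- as.vector(outer(qs, ps, `-`))
        acc[[w]] <- d[d >= 1L]
      } else {
        acc[[w]] <- as.vector(outer(ps, n + 1L - qs, `+`))
      }
    }
    diags <- unique(c(diags, unlist(acc)))
    calls <- .scan_repeat_diagonals(s, kind, diags, n, min_len, max_mismatch)
    if (nrow(calls)) out[[length(out) + 1L]] <- calls
  }
  out <- if (length(out)) do.call(rbind, out) else empty
  if (!nrow(out)) return(empty)
  out <- .drop_nested_pairs(out)
  out <- out[order(-out$length, out$kind, out$start1), , drop = FALSE]
  out <- out[seq_len(min(max_results, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive maximal-window scan of the given diagonals for one orientation.
#' @keywords internal
.scan_repeat_diagonals <- function(s, kind, diags, n, min_len, max_mismatch) {
  rows <- list()
  for (dg in diags) {
    if (kind %in% c("F", "C")) {
      i <- seq_len(n - dg)
      a <- s[i]; b <- s[i + dg]
      if (kind == "C") b <- complement_chars(b)
      v <- a == b & is_base(s[i]) & is_base(s[i + dg])
      offset <- 0L
    } else {
      amin <- max(1L, dg - n); amax <- (dg - 1L) %/% 2L
      if (amax < amin) next
      aidx <- seq.int(amin, amax)
      b <- s[dg - aidx]
      if (kind == "P") b <- complement_chars(b)
      v <- s[aidx] == b & is_base(s[aidx]) & is_base(s[dg - aidx])
      offset <- amin - 1L
    }
    wins <- .maximal_windows(v, max_mismatch, min_len)
    if (!nrow(wins)) next
    for (w in seq_len(nrow(wins))) {
      lo <- wins[w, "start"] + offset; hi <- wins[w, "end"] + offset
      len <- hi - lo + 1L
      mm <- wins[w, "mismatches"]
      if (kind %in% c("F", "C")) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, start1 = lo, end1 = hi,
          start2 = lo + dg, end2 = hi + dg,
          length = len, mismatches = mm, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, start1 = lo, end1 = hi,
          start2 = dg - hi, end2 = dg - lo,
          length = len, mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0),
               length = integer(0), mismatches = integer(0))
}

# Maximal windows of a logical match vector containing <= mm mismatches and
# spanning at least min_len, trimmed so both ends are matches. Returns
# start/end/mismatches (local 1-based coordinates).
#' @keywords internal
.maximal_windows <- function(v, mm, min_len = 1L) {
  L <- length(v)
  mp <- which(!v)
  r <- length(mp)
  if (r <= mm) {
    lo <- 1L; hi <- L
  } else {
    g <- 0:(r - mm)
    lo <- c(0L, mp)[g + 1L] + 1L
    hi <- c(mp, L + 1L)[g + mm + 1L] - 1L
  }
  keep <- hi - lo + 1L >= min_len  # filter before the per-window trim loop
  lo <- lo[keep]; hi <- hi[keep]
  out <- matrix(integer(0), ncol = 3L,
                dimnames = list(NULL, c("start", "end", "mismatches")))
  seen <- character(0)
  for (w in seq_along(lo)) {
    a <- lo[w]; b <- hi[w]
    while (a <= b && !v[a]) a <- a + 1L
    while (b >= a && !v[b]) b <- b - 1L
    if (b < a || b - a + 1L < min_len) next
    key <- paste(a, b)
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- rbind(out, c(a, b, sum(!v[a:b])))
  }
  out
}

# Suppress pairs whose both occurrences are contained within a longer pair of
# the same kind.
#' @keywords internal
.drop_nested_pairs <- function(calls) {
  keep <- rep(TRUE, nrow(calls))
  ord <- order(-calls$length)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    same <- which(calls$kind == calls$kind[i] & keep & calls$length < calls$length[i])
    if (!length(same)) next
    nested <- calls$start1[same] >= calls$start1[i] & calls$end1[same] <= calls$end1[i] &
      calls$start2[same] >= calls$start2[i] & calls$end2[same] <= calls$end2[i]
    keep[same[nested]] <- FALSE
  }
  calls[keep, , drop = FALSE]
}

#' Find approximate tandem repeat arrays
#'
#' Bespoke period scan: for each candidate period p the sequence is compared
#' with itself shifted by p; runs of agreement, merged across isolated
#' disagreements while the overall mismatch fraction stays within
#' `max_mismatch_frac`, define candidate arrays. Arrays shorter than
#' `min_span`, with fewer than `min_copies` copies, or whose consensus unit
#' is periodic at a smaller reported period are dropped; overlapping calls at
#' different periods keep the longest span (ties: smallest period).
#'
#' @param sequence DNA string
#' @param min_period smallest period (default 7, above the SSR range)
#' @param max_period largest period scanned (default 330)
#' @param min_copies minimum (possibly fractional) copy number (default 2)
#' @param min_span minimum array span in bp (default 22)
#' @param max_mismatch_frac allowed disagreement fraction (default 0.2)
#' @return data.frame with columns period, copies, start, end, span,
#'   identity, consensus
#' @export
find_tandem_repeats <- function(sequence, min_period = 7L, max_period = 330L,
                                min_copies = 2, min_span = 22L,
                                max_mismatch_frac = 0.2) {
  s <- seq_chars(toupper(sequence))
  n <- length(s)
  rows <- list()
  for (p in seq.int(min_period, min(max_period, n %/% 2L))) {
    eq <- s[seq_len(n - p)] == s[seq.int(p + 1L, n)] &
      is_base(s[seq_len(n - p)]) & is_base(s[seq.int(p + 1L, n)])
    runs <- true_runs(eq)
    if (!nrow(runs)) next
    # seed on exact-agreement runs long enough to belong to a real array,
    # then grow each seed across isolated disagreements while the overall
    # mismatch fraction stays within budget
    seed_min <- max(6L, min(p, 12L))
    seeds <- which(runs[, "end"] - runs[, "start"] + 1L >= seed_min)
    if (!length(seeds)) next
    merged <- .grow_tandem_seeds(runs, seeds, max_mismatch_frac, p)
    for (i in seq_len(nrow(merged))) {
      span <- merged[i, "end"] - merged[i, "start"] + 1L + p
      copies <- span / p
      if (span < min_span || copies < min_copies) next
      start <- merged[i, "start"]; end <- start + span - 1L
      ident <- mean(eq[merged[i, "start"]:merged[i, "end"]])
      cons <- .tandem_consensus(s, start, end, p)
      # arrays whose unit self-agrees at a shift in the SSR range (<= 6) are
      # microsatellite territory, not tandem-repeat calls
      if (.weak_period(cons) <= 6L) next
      rows[[length(rows) + 1L]] <- data.frame(
        period = p, copies = copies, start = start, end = end, span = span,
        identity = ident, consensus = cons, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(period = integer(0), copies = numeric(0), start = integer(0),
               end = integer(0), span = integer(0), identity = numeric(0),
               consensus = character(0))
  if (nrow(out) > 1L) out <- .dedupe_tandem(out)
  rownames(out) <- NULL
  out
}

# Grow seed runs outward over neighbouring runs while the disagreement
# fraction of the covered window stays within frac. Returns deduplicated
# [start, end] windows in eq-coordinates.
#' @keywords internal
.grow_tandem_seeds <- function(runs, seeds, frac, p) {
  nr <- nrow(runs)
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  seen <- character(0)
  run_len <- runs[, "end"] - runs[, "start"] + 1L
  for (si in seeds) {
    lo <- si; hi <- si
    repeat {
      grew <- FALSE
      for (dir in c(1L, -1L)) {
        nxt <- if (dir == 1L) hi + 1L else lo - 1L
        if (nxt < 1L || nxt > nr) next
        a <- runs[min(lo, nxt), "start"]; b <- runs[max(hi, nxt), "end"]
        window <- b - a + 1L
        mism <- window - sum(run_len[min(lo, nxt):max(hi, nxt)])
        if (mism / (window + p) <= frac) {
          if (dir == 1L) hi <- nxt else lo <- nxt
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    key <- paste(runs[lo, "start"], runs[hi, "end"])
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- rbind(out, c(runs[lo, "start"], runs[hi, "end"]))
  }
  out
}

# column-majority consensus over the full copies of an array
#' @keywords internal
.tandem_consensus <- function(s, start, end, p) {
  ncopy <- (end - start + 1L) %/% p
  m <- matrix(s[seq.int(start, start + ncopy * p - 1L)], nrow = p)
  chars_seq(apply(m, 1L, function(col) names(which.max(table(col)))))
}

#' @keywords internal
.dedupe_tandem <- function(out) {
  ord <- order(-out$span, out$period)
  keep <- logical(nrow(out))
  taken <- matrix(integer(0), ncol = 2L)
  for (i in ord) {
    a <- out$start[i]; b <- out$end[i]
    overlap <- FALSE
    if (nrow(taken)) {
      ov <- pmin(taken[, 2L], b) - pmax(taken[, 1L], a) + 1L
      overlap <- any(ov > 0.5 * (b - a + 1L))
    }
    if (!overlap) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(a, b))
    }
  }
  out[keep, , drop = FALSE][order(out$start[keep]), , drop = FALSE]
}

#' Attribute repeat calls to structural and functional regions
#'
#' Each call is assigned its LSC/SSC/IR region and CDS/intron/IGS class by
#' span midpoint; calls straddling a region junction are flagged. For
#' dispersed repeats pass occurrence rows (see [dispersed_occurrences()]) so
#' each copy is counted once.
#'
#' @param calls data.frame with columns `start`, `end` (genome coordinates)
#' @param partition the genome's [detect_partition()] result (NULL to skip
#'   structural attribution)
#' @param annotation the genome's [annotate_regions()] result (NULL to skip
#'   functional attribution)
#' @return `calls` with added columns structural_region, functional_region,
#'   straddles_junction; attributes `structural_counts` and
#'   `functional_counts` hold the distribution tables
#' @export
attribute_repeats <- function(calls, partition = NULL, annotation = NULL) {
  n <- nrow(calls)
  gl <- if (!is.null(partition)) partition$genome_length else
    if (!is.null(annotation)) annotation$length else NA_integer_
  mid <- ((calls$start + (calls$end - calls$start) %/% 2L - 1L) %% gl) + 1L
  if (!is.null(partition)) {
    calls$structural_region <- structural_region_of(mid, partition)
    sr_start <- structural_region_of(((calls$start - 1L) %% gl) + 1L, partition)
    sr_end <- structural_region_of(((calls$end - 1L) %% gl) + 1L, partition)
    calls$straddles_junction <- sr_start != sr_end
  }
  if (!is.null(annotation)) {
    calls$functional_region <- annotation$class[mid]
  }
  if (!is.null(partition))
    attr(calls, "structural_counts") <- table(calls$structural_region)
  if (!is.null(annotation))
    attr(calls, "functional_counts") <- table(calls$functional_region)
  calls
}

#' Expand dispersed repeat pairs to one row per occurrence
#'
#' @param calls data.frame from [find_dispersed_repeats()]
#' @return data.frame with columns kind, copy (1 or 2), start, end, length
#' @export
dispersed_occurrences <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(kind = character(0), copy = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  rbind(
    data.frame(kind = calls$kind, copy = 1L, start = calls$start1,
               end = calls$end1, length = calls$length, stringsAsFactors = FALSE),
    data.frame(kind = calls$kind, copy = 2L, start = calls$start2,
               end = calls$end2, length = calls$length, stringsAsFactors = FALSE)
  )
}

#' Write repeat calls as BED
#'
#' @param calls data.frame with `start`, `end` and a name-able column set
#' @param accession BED chrom name
#' @param path output path
#' @param name_col column used for the BED name field
#' @return `path`, invisibly
#' @export
write_repeats_bed <- function(calls, accession, path, name_col = NULL) {
  if (!nrow(calls)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if (!is.null(name_col) && name_col %in% names(calls)) calls[[name_col]] else "repeat"
  writeLines(sprintf("%s\t%d\t%d\t%s", accession, calls$start - 1L, calls$end, nm), path)
  invisible(path)
}
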