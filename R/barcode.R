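# Species-diagnostic SNP discovery and allele-specific PCR marker design:
# columns fixed for one allele in every accession of the target species and
# absent from all background accessions become 3'-anchor candidates for
# allele-specific primers; a control pair is drawn from fully conserved
# sequence; both are validated by in-silico PCR with a strict 3'-match rule.

#' Find target-species-diagnostic SNP columns
#'
#' A diagnostic column is one where (i) every target-species row carries the
#' same base (intraspecific fixation), (ii) no background row carries that
#' base, and (iii) no row has a gap or N. Flank conservation (fraction of
#' columns invariant across all rows within +/- `flank`) is attached and the
#' result is sorted by flank conservation (descending) then reference
#' coordinate.
#'
#' @param aln a [plast_alignment()]
#' @param target_species species name; must have at least one accession, and
#'   at least one background accession must remain
#' @param min_flank_conservation keep columns whose flank conservation is at
#'   least this (default 0.8)
#' @param flank half-width of the conservation window in columns (default 25)
#' @return data.frame with columns column, ref_pos, target_allele,
#'   background_alleles, flank_conservation
#' @export
find_diagnostic_snps <- function(aln, target_species, min_flank_conservation = 0.8,
                                 flank = 25L) {
  tgt <- accessions_of(aln, target_species)
  if (!length(tgt)) stop("target species absent from alignment: ", target_species)
  bg <- setdiff(rownames(aln$matrix), tgt)
  if (!length(bg)) stop("no background accessions besides the target species")
  m <- aln$matrix
  tm <- m[tgt, , drop = FALSE]
  bm <- m[bg, , drop = FALSE]

  clean <- colSums(!is_base(m)) == 0L
  fixed_target <- colSums(tm == tm[rep(1L, nrow(tm)), , drop = FALSE]) == nrow(tm)
  allele <- tm[1L, ]
  bg_has_allele <- colSums(t(t(bm) == allele)) > 0L
  cand <- which(clean & fixed_target & !bg_has_allele)
  if (!length(cand)) {
    return(data.frame(column = integer(0), ref_pos = integer(0),
                      target_allele = character(0), background_alleles = character(0),
                      flank_conservation = numeric(0)))
  }
  invariant <- .invariant_columns(aln)
  fc <- vapply(cand, function(col) {
    win <- setdiff(seq.int(max(1L, col - flank), min(ncol(m), col + flank)), col)
    mean(invariant[win])
  }, numeric(1))
  out <- data.frame(
    column = cand,
    ref_pos = aln$column_map[cand],
    target_allele = allele[cand],
    background_alleles = vapply(cand, function(col)
      paste(sort(unique(bm[, col])), collapse = ","), ""),
    flank_conservation = fc,
    stringsAsFactors = FALSE
  )
  out <- out[out$flank_conservation >= min_flank_conservation, , drop = FALSE]
  out <- out[order(-out$flank_conservation, out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# columns where every row carries the same A/C/G/T base
#' @keywords internal
.invariant_columns <- function(aln) {
  m <- aln$matrix
  first <- m[1L, ]
  colSums(m == m[rep(1L, nrow(m)), , drop = FALSE]) == nrow(m) & is_base(first)
}

#' Default primer design constraints
#'
#' @param primer_len allowed primer lengths (default 18-27 nt)
#' @param gc allowed GC fraction range (default 0.35-0.65)
#' @param tm allowed melting temperature range in Celsius (default 52-62)
#' @param product allowed product size range in bp (default 300-2500)
#' @return named list of constraints
#' @export
primer_constraints <- function(primer_len = 18:27, gc = c(0.35, 0.65),
                               tm = c(52, 62), product = c(300L, 2500L)) {
  list(primer_len = primer_len, gc = gc, tm = tm, product = product)
}

#' Design allele-specific diagnostic primer pairs
#'
#' Enumerates ordered pairs of diagnostic SNPs whose spacing fits the product
#' range. The forward primer is target-genome sequence ending 3' on the left
#' anchor allele; the reverse primer is the reverse complement of target
#' sequence beginning at the right anchor, i.e. also ending 3' on its
#' diagnostic allele. Every non-anchor primer position must be invariant
#' across all accessions (so only the anchor discriminates). Candidates are
#' filtered by length/GC/Tm/product constraints and ranked by Tm balance then
#' mean anchor flank conservation.
#'
#' @param aln a [plast_alignment()]
#' @param snps data.frame from [find_diagnostic_snps()]
#' @param constraints list from [primer_constraints()]
#' @param max_pairs cap on returned pairs (default 10)
#' @return data.frame of primer pairs (forward, reverse, coordinates on the
#'   target genome, per-primer Tm and GC, product_size, role "diagnostic").
#'   Empty with a `message` attribute suggesting single-anchor mode when no
#'   SNP pair satisfies the spacing.
#' @export
design_diagnostic_pair <- function(aln, snps, constraints = primer_constraints(),
                                   max_pairs = 10L) {
  empty <- data.frame(forward = character(0), reverse = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      rev_start = integer(0), rev_end = integer(0),
                      anchor_fwd = integer(0), anchor_rev = integer(0),
                      product_size = integer(0), tm_fwd = numeric(0),
                      tm_rev = numeric(0), gc_fwd = numeric(0), gc_rev = numeric(0),
                      score = numeric(0), role = character(0))
  if (nrow(snps) < 2L) {
    attr(empty, "message") <- "fewer than two diagnostic SNPs; consider single-anchor mode"
    return(empty)
  }
  target_acc <- .target_accession(aln, snps)
  tpos <- row_position_map(aln, target_acc)
  tseq <- seq_chars(ungapped_sequence(aln, target_acc))
  invariant <- .invariant_columns(aln)
  snps <- snps[order(snps$column), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(snps) - 1L)) {
    for (j in seq.int(i + 1L, nrow(snps))) {
      p1 <- tpos[snps$column[i]]; p2 <- tpos[snps$column[j]]
      if (is.na(p1) || is.na(p2)) next
      # outer product bounds over the allowed primer lengths
      span <- p2 - p1 + 1L
      if (span + 2L * max(constraints$primer_len) - 2L < constraints$product[1L] ||
          span + 2L * min(constraints$primer_len) - 2L > constraints$product[2L]) next
      fwd <- .anchored_primer(aln, snps$column[i], tpos, tseq, invariant,
                              constraints, direction = "forward")
      rev_ <- .anchored_primer(aln, snps$column[j], tpos, tseq, invariant,
                               constraints, direction = "reverse")
      if (is.null(fwd) || is.null(rev_)) next
      product <- rev_$end - fwd$start + 1L
      if (product < constraints$product[1L] || product > constraints$product[2L]) next
      score <- -abs(fwd$tm - rev_$tm) +
        mean(c(snps$flank_conservation[i], snps$flank_conservation[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        forward = fwd$seq, reverse = rev_$seq,
        fwd_start = fwd$start, fwd_end = fwd$end,
        rev_start = rev_$start, rev_end = rev_$end,
        anchor_fwd = p1, anchor_rev = p2,
        product_size = product, tm_fwd = fwd$tm, tm_rev = rev_$tm,
        gc_fwd = fwd$gc, gc_rev = rev_$gc, score = score,
        role = "diagnostic", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    attr(empty, "message") <-
      "no diagnostic SNP pair fits the product range; consider single-anchor mode (one anchored + one conserved primer)"
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  out <- out[seq_len(min(max_pairs, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
.target_accession <- function(aln, snps) {
  # any accession carrying the target allele at the first diagnostic column
  col <- snps$column[1L]
  rownames(aln$matrix)[aln$matrix[, col] == snps$target_allele[1L]][1L]
}

# Build one anchored primer: target sequence ending 3' on the anchor.
# direction "forward": genome [anchor - len + 1, anchor], as-is;
# direction "reverse": genome [anchor, anchor + len - 1], reverse complement.
# All non-anchor columns under the primer must be invariant.
#' @keywords internal
.anchored_primer <- function(aln, anchor_col, tpos, tseq, invariant,
                             constraints, direction) {
  anchor_pos <- tpos[anchor_col]
  col_of <- match(seq_along(tseq), tpos)  # target position -> alignment column
  for (len in sort(constraints$primer_len, decreasing = TRUE)) {
    if (direction == "forward") {
      a <- anchor_pos - len + 1L; b <- anchor_pos
    } else {
      a <- anchor_pos; b <- anchor_pos + len - 1L
    }
    if (a < 1L || b > length(tseq)) next
    cols <- col_of[a:b]
    body_cols <- setdiff(cols, anchor_col)
    if (anyNA(cols) || !all(invariant[body_cols])) next
    primer <- chars_seq(tseq[a:b])
    if (direction == "reverse") primer <- revcomp(primer)
    gc <- gc_fraction(seq_chars(primer))
    if (gc < constraints$gc[1L] || gc > constraints$gc[2L]) next
    tm <- primer_tm(primer)
    if (tm < constraints$tm[1L] || tm > constraints$tm[2L]) next
    return(list(seq = primer, start = a, end = b, tm = tm, gc = gc))
  }
  NULL
}

#' Design a conserved control primer pair
#'
#' Both primers are drawn from maximal runs of columns invariant across every
#' accession, with the product size as close as possible to `target_product`.
#' Deterministic first-best: candidates are ranked by |product - target|,
#' then Tm balance.
#'
#' @param aln a [plast_alignment()]
#' @param constraints list from [primer_constraints()]
#' @param target_product desired product size in bp (default 400)
#' @return one-row data.frame in the [design_diagnostic_pair()] layout with
#'   role "control"
#' @export
design_control_pair <- function(aln, constraints = primer_constraints(),
                                target_product = 400L) {
  invariant <- .invariant_columns(aln)
  min_len <- min(constraints$primer_len)
  runs <- true_runs(invariant)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_len, , drop = FALSE]
  if (!nrow(runs)) stop("no invariant run long enough for a control primer")
  ref_acc <- aln$reference_id
  rpos <- row_position_map(aln, ref_acc)
  rseq <- seq_chars(ungapped_sequence(aln, ref_acc))
  len <- min_len + (max(constraints$primer_len) - min_len) %/% 2L  # mid-range length

  best <- NULL
  for (i in seq_len(nrow(runs))) {
    for (j in seq.int(i, nrow(runs))) {
      # forward primer at the start of run i, reverse at the end of run j
      fa_col <- runs[i, "start"]; fb_col <- fa_col + len - 1L
      rb_col <- runs[j, "end"]; ra_col <- rb_col - len + 1L
      if (fb_col > runs[i, "end"] || ra_col < runs[j, "start"]) next
      fa <- rpos[fa_col]; fb <- rpos[fb_col]
      ra <- rpos[ra_col]; rb <- rpos[rb_col]
      if (anyNA(c(fa, fb, ra, rb)) || ra <= fb) next
      product <- rb - fa + 1L
      if (product < constraints$product[1L] || product > constraints$product[2L]) next
      fwd <- chars_seq(rseq[fa:fb])
      rev_ <- revcomp(chars_seq(rseq[ra:rb]))
      gcf <- gc_fraction(seq_chars(fwd)); gcr <- gc_fraction(seq_chars(rev_))
      if (gcf < constraints$gc[1L] || gcf > constraints$gc[2L]) next
      if (gcr < constraints$gc[1L] || gcr > constraints$gc[2L]) next
      tmf <- primer_tm(fwd); tmr <- primer_tm(rev_)
      if (tmf < constraints$tm[1L] || tmf > constraints$tm[2L]) next
      if (tmr < constraints$tm[1L] || tmr > constraints$tm[2L]) next
      cand <- list(forward = fwd, reverse = rev_, fa = fa, fb = fb, ra = ra, rb = rb,
                   product = product, tmf = tmf, tmr = tmr, gcf = gcf, gcr = gcr,
                   badness = abs(product - target_product) + abs(tmf - tmr))
      if (is.null(best) || cand$badness < best$badness) {
        # reject pairs that amplify more than once from the reference genome
        # (e.g. primers inside the IR amplify from both copies)
        amp <- in_silico_pcr(chars_seq(rseq), cand, max_product = 2L * product)
        if (nrow(amp) == 1L) best <- cand
      }
    }
  }
  if (is.null(best)) stop("no conserved primer pair satisfies the constraints")
  data.frame(forward = best$forward, reverse = best$reverse,
             fwd_start = best$fa, fwd_end = best$fb,
             rev_start = best$ra, rev_end = best$rb,
             anchor_fwd = NA_integer_, anchor_rev = NA_integer_,
             product_size = best$product, tm_fwd = best$tmf, tm_rev = best$tmr,
             gc_fwd = best$gcf, gc_rev = best$gcr, score = -best$badness,
             role = "control", stringsAsFactors = FALSE)
}

#' In-silico PCR
#'
#' Finds all convergent primer binding-site pairs within `max_product` on a
#' (circular) template. A primer binds a site when the full-length alignment
#' has at most `max_internal_mismatch` mismatches and, when
#' `three_prime_strict`, zero mismatches in the 3'-terminal 3 bases -- the
#' allele-specific PCR failure model. Both template orientations are scanned.
#'
#' @param template a [plastome_record()] or DNA string
#' @param pair one-row data.frame with `forward` and `reverse` primer columns
#'   (or a list with those fields)
#' @param max_product maximum product size (default 3000)
#' @param three_prime_strict enforce the 3'-terminal exact-match rule
#' @param max_internal_mismatch mismatch allowance outside the 3' terminus
#' @param circular treat the template as circular (default TRUE for records)
#' @return data.frame of amplicons: start, end (template coordinates of the
#'   product), size, fwd_mismatches, rev_mismatches, strand
#' @export
in_silico_pcr <- function(template, pair, max_product = 3000L,
                          three_prime_strict = TRUE, max_internal_mismatch = 2L,
                          circular = TRUE) {
  seq_str <- if (inherits(template, "plastome_record")) template$sequence else toupper(template)
  n <- nchar(seq_str)
  ext <- if (circular) min(n, max_product) else 0L
  s <- seq_chars(paste0(seq_str, substr(seq_str, 1L, ext)))
  fwd <- toupper(if (is.data.frame(pair)) pair$forward[1L] else pair$forward)
  rev_ <- toupper(if (is.data.frame(pair)) pair$reverse[1L] else pair$reverse)

  hits <- function(primer) {
    .primer_sites(s, primer, three_prime_strict, max_internal_mismatch)
  }
  f_plus <- hits(fwd)                 # forward primer on plus strand
  r_minus <- hits(revcomp(rev_))      # reverse primer (binds minus strand)
  f_minus <- hits(revcomp(fwd))       # swapped orientation
  r_plus <- hits(rev_)

  out <- list()
  collect <- function(left, right, llen, rlen, strand) {
    for (i in seq_len(nrow(left))) {
      a <- left$start[i]
      ok <- right$start > a & (right$start + rlen - 1L) - a + 1L <= max_product
      for (j in which(ok)) {
        b <- right$start[j] + rlen - 1L
        if (a > n) next  # canonical copy only on circular templates
        out[[length(out) + 1L]] <<- data.frame(
          start = a, end = b, size = b - a + 1L,
          fwd_mismatches = left$mismatches[i], rev_mismatches = right$mismatches[j],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  collect(f_plus, r_minus, nchar(fwd), nchar(rev_), "+")
  collect(r_plus, f_minus, nchar(rev_), nchar(fwd), "-")
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), size = integer(0),
               fwd_mismatches = integer(0), rev_mismatches = integer(0),
               strand = character(0))
  # deduplicate circular images
  if (nrow(out)) {
    key <- paste(((out$start - 1L) %% n) + 1L, out$size, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# All binding sites of a primer on a character-vector template (plus strand,
# 5'->3' left to right).
#' @keywords internal
.primer_sites <- function(s, primer, three_prime_strict, max_internal_mismatch) {
  p <- seq_chars(primer)
  L <- length(p)
  n <- length(s)
  if (n < L) return(data.frame(start = integer(0), mismatches = integer(0)))
  starts <- seq_len(n - L + 1L)
  mism <- integer(length(starts))
  tail3 <- integer(length(starts))
  for (t in seq_len(L)) {
    ne <- s[starts + t - 1L] != p[t]
    mism <- mism + ne
    if (t > L - 3L) tail3 <- tail3 + ne
  }
  ok <- if (three_prime_strict) {
    tail3 == 0L & (mism - tail3) <= max_internal_mismatch
  } else {
    mism <= max_internal_mismatch
  }
  data.frame(start = starts[ok], mismatches = mism[ok])
}

#' Nearest-neighbor primer melting temperature
#'
#' SantaLucia (1998) unified nearest-neighbor thermodynamics with the
#' entropic salt correction (0.368 x (N-1) x ln[Na+]); Tm for a
#' non-self-complementary oligo at concentration `primer_conc` is
#' 1000 dH / (dS + R ln(C/4)) - 273.15.
#'
#' @param primer primer sequence (5'->3')
#' @param na_conc monovalent cation concentration in M (default 0.05)
#' @param primer_conc primer concentration in M (default 5e-7)
#' @return melting temperature in degrees Celsius
#' @export
primer_tm <- function(primer, na_conc = 0.05, primer_conc = 5e-7) {
  nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
             GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
             TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
  nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4, CT = -21.0,
             GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
             TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9)
  p <- seq_chars(toupper(primer))
  L <- length(p)
  if (L < 8L) stop("primer too short for nearest-neighbor Tm")
  steps <- paste0(p[-L], p[-1L])
  dh <- sum(nn_dh[steps])
  ds <- sum(nn_ds[steps])
  for (termbase in p[c(1L, L)]) {
    if (termbase %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (L - 1) * log(na_conc)
  1000 * dh / (ds + 1.987 * log(primer_conc / 4)) - 273.15
}
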