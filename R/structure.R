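# Quadripartite architecture: detection of the inverted-repeat pair by
# seed-and-extend on k-mer matches against the reverse complement, per-region
# composition, gene content summaries and IR junction comparison.

#' Detect the quadripartite partition of a plastome sequence
#'
#' Finds the maximal-length pair of inverted near-identical segments
#' consistent with a quadripartite layout (seed k-mers matched against the
#' reverse complement, extended to maximal identity blocks along the shared
#' anti-diagonal; exact identity by default). The longer single-copy region is
#' labelled LSC; IRb is the IR copy that follows the LSC in circular order.
#' Works across the linearization origin.
#'
#' @param sequence DNA string (circular, linearized at an arbitrary origin)
#' @param min_ir_len minimum acceptable IR length in bp (default 1000)
#' @param max_mismatch_frac allowed mismatch fraction between the two IR
#'   copies (default 0: assemblies emit identical IRs)
#' @param seed_k seed k-mer length (default 25)
#' @return an object of class `quadripartite_partition`: list of `lsc`, `irb`,
#'   `ssc`, `ira` (each `c(start, end)`, 1-based closed, start > end when the
#'   region wraps the origin), the four lengths and `genome_length`
#' @export
detect_partition <- function(sequence, min_ir_len = 1000L, max_mismatch_frac = 0,
                             seed_k = 25L) {
  s <- seq_chars(toupper(sequence))
  n <- length(s)
  if (n < 2L * min_ir_len)
    stop(.no_ir_condition(sprintf("sequence of %d bp cannot hold two IR copies of >= %d bp",
                                  n, min_ir_len)))
  cs <- complement_chars(s)
  seq_str <- chars_seq(s)
  rc <- revcomp(seq_str)
  k <- min(seed_k, max(4L, min_ir_len %/% 4L))

  # index every k-mer of the reverse complement; probe with strided k-mers of
  # the forward sequence (stride k still hits any inverted block >= 2k - 1)
  rc_starts <- seq_len(n - k + 1L)
  rc_kmers <- substring(rc, rc_starts, rc_starts + k - 1L)
  idx <- split(rc_starts, rc_kmers)
  probe_starts <- seq.int(1L, n - k + 1L, by = k)
  probe_kmers <- substring(seq_str, probe_starts, probe_starts + k - 1L)
  hits <- idx[probe_kmers]
  antidiags <- integer(0)
  for (i in seq_along(hits)) {
    q <- hits[[i]]
    if (is.null(q)) next
    antidiags <- c(antidiags, probe_starts[i] + n - q + 1L)
  }
  # also probe across the origin so an IR spanning the stored origin seeds
  wrap_probe <- paste0(substr(seq_str, n - k + 2L, n), substr(seq_str, 1L, k - 1L))
  if (n > k) {
    wk <- substring(wrap_probe, seq_len(k - 1L), seq_len(k - 1L) + k - 1L)
    for (j in seq_along(wk)) {
      q <- idx[[wk[j]]]
      if (is.null(q)) next
      antidiags <- c(antidiags, (n - k + 1L + j) + n - q + 1L)
    }
  }
  antidiags <- unique(antidiags)

  best <- NULL
  for (c0 in antidiags) {
    cand <- .scan_antidiagonal(s, cs, c0, n, min_ir_len, max_mismatch_frac)
    for (cd in cand) {
      if (is.null(best) ||
          cd$len > best$len ||
          (cd$len == best$len && .min_sc(cd, n) > .min_sc(best, n))) {
        best <- cd
      }
    }
  }
  if (is.null(best))
    stop(.no_ir_condition(sprintf("no inverted repeat of >= %d bp found", min_ir_len)))

  .partition_from_pair(best, n)
}

#' @keywords internal
.no_ir_condition <- function(msg) {
  errorCondition(msg, class = c("noIRFound", "plastomarker_error"))
}

# Scan one anti-diagonal c (s[a] pairs with complement(s[c - a]), indices on
# the circle) and return disjoint inverted pairs of length >= min_len.
#' @keywords internal
.scan_antidiagonal <- function(s, cs, c0, n, min_len, max_mismatch_frac) {
  # a runs over the full circle; partner b = (c0 - a - 1) mod n + 1
  a <- seq_len(n)
  b <- ((c0 - a - 1L) %% n) + 1L
  v <- s[a] == cs[b] & is_base(s[a]) & is_base(s[b])
  # restrict to one half of the anti-diagonal (each pair appears twice);
  # work on the doubled vector so runs crossing position 1 are caught
  vv <- c(v, v)
  runs <- true_runs(vv)
  if (!nrow(runs)) return(list())
  if (max_mismatch_frac > 0 && nrow(runs) > 1L) {
    runs <- .merge_runs(vv, runs, max_mismatch_frac)
  }
  out <- list()
  for (i in seq_len(nrow(runs))) {
    len_run <- runs[i, "end"] - runs[i, "start"] + 1L
    if (len_run < min_len || runs[i, "start"] > n) next
    len <- min(len_run, n)  # degenerate fully-matching circle
    a1 <- ((runs[i, "start"] - 1L) %% n) + 1L
    a2 <- ((a1 + len - 2L) %% n) + 1L
    b2 <- ((c0 - a1 - 1L) %% n) + 1L  # partner interval end
    b1 <- ((c0 - (a1 + len - 1L) - 1L) %% n) + 1L
    # the run covers both copies on the anti-diagonal; take the copy pair once
    # by splitting the run at its centre when it self-pairs
    if (.circ_overlap(a1, a2, b1, b2, n)) {
      half <- len %/% 2L
      if (half < min_len) next
      a2 <- ((a1 + half - 2L) %% n) + 1L
      b1 <- ((c0 - (a1 + half - 1L) - 1L) %% n) + 1L
      len <- half
      if (.circ_overlap(a1, a2, b1, b2, n)) next
    }
    out[[length(out) + 1L]] <- list(i1 = c(a1, a2), i2 = c(b1, b2), len = len)
  }
  out
}

#' @keywords internal
.merge_runs <- function(v, runs, frac) {
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    last <- nrow(merged)
    span <- runs[i, "end"] - merged[last, "start"] + 1L
    mism <- sum(!v[merged[last, "start"]:runs[i, "end"]])
    if (mism / span <= frac) {
      merged[last, "end"] <- runs[i, "end"]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  merged
}

#' @keywords internal
.circ_overlap <- function(a1, a2, b1, b2, n) {
  pos_a <- ((seq.int(0L, circ_length(a1, a2, n) - 1L) + a1 - 1L) %% n) + 1L
  pos_b <- ((seq.int(0L, circ_length(b1, b2, n) - 1L) + b1 - 1L) %% n) + 1L
  length(intersect(pos_a, pos_b)) > 0L
}

#' @keywords internal
.min_sc <- function(cand, n) {
  g1 <- (cand$i2[1L] - cand$i1[2L] - 1L) %% n
  g2 <- (cand$i1[1L] - cand$i2[2L] - 1L) %% n
  min(g1, g2)
}

#' @keywords internal
.partition_from_pair <- function(cand, n) {
  # two IR intervals on the circle; the two gaps between them are the
  # single-copy regions. LSC = the longer gap; IRb = IR copy after the LSC.
  iA <- cand$i1; iB <- cand$i2
  gapAB <- (iB[1L] - iA[2L] - 1L) %% n  # gap following copy A
  gapBA <- (iA[1L] - iB[2L] - 1L) %% n  # gap following copy B
  wrap1 <- function(p) ((p - 1L) %% n) + 1L
  if (gapBA >= gapAB) {
    lsc <- c(wrap1(iB[2L] + 1L), wrap1(iA[1L] - 1L)); irb <- iA
    ssc <- c(wrap1(iA[2L] + 1L), wrap1(iB[1L] - 1L)); ira <- iB
  } else {
    lsc <- c(wrap1(iA[2L] + 1L), wrap1(iB[1L] - 1L)); irb <- iB
    ssc <- c(wrap1(iB[2L] + 1L), wrap1(iA[1L] - 1L)); ira <- iA
  }
  structure(list(
    lsc = unname(lsc), irb = unname(irb), ssc = unname(ssc), ira = unname(ira),
    lsc_length = unname(circ_length(lsc[1L], lsc[2L], n)),
    ir_length = unname(cand$len),
    ssc_length = unname(circ_length(ssc[1L], ssc[2L], n)),
    genome_length = n
  ), class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite_partition> LSC %s | IRb %s | SSC %s | IRa %s bp (genome %s)\n",
              format(x$lsc_length, big.mark = ","), format(x$ir_length, big.mark = ","),
              format(x$ssc_length, big.mark = ","), format(x$ir_length, big.mark = ","),
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Structural region (LSC/SSC/IR) of genome positions
#'
#' @param pos integer vector of 1-based positions
#' @param partition a [detect_partition()] result
#' @return character vector over {"LSC","SSC","IR"}
#' @export
structural_region_of <- function(pos, partition) {
  n <- partition$genome_length
  inside <- function(p, iv) {
    if (iv[1L] <= iv[2L]) p >= iv[1L] & p <= iv[2L] else p >= iv[1L] | p <= iv[2L]
  }
  out <- rep(NA_character_, length(pos))
  out[inside(pos, partition$lsc)] <- "LSC"
  out[inside(pos, partition$ssc)] <- "SSC"
  out[inside(pos, partition$irb) | inside(pos, partition$ira)] <- "IR"
  out
}

#' Rotate a record so that the LSC starts at position 1
#'
#' Canonical plastome linearization (LSC, IRb, SSC, IRa in order).
#'
#' @param record a [plastome_record()]
#' @param partition the record's [detect_partition()] result
#' @return list with the rotated `record` and its re-detected `partition`
#' @export
canonicalize_plastome <- function(record, partition) {
  rec <- rotate_record(record, partition$lsc[1L])
  part <- detect_partition(rec$sequence,
                           min_ir_len = min(partition$ir_length, 1000L))
  list(record = rec, partition = part)
}

#' Per-region and per-feature-class GC content
#'
#' GC is (G+C)/(A+C+G+T); Ns are excluded from the denominator. The total is
#' the base-weighted mean of the four regions by construction.
#'
#' @param record a [plastome_record()]
#' @param partition the record's partition
#' @return data.frame with columns `region`, `length`, `gc` covering LSC, IRb,
#'   SSC, IRa, total, and (when features are present) CDS, tRNA, rRNA
#' @export
region_gc <- function(record, partition) {
  s <- seq_chars(record$sequence)
  n <- record$length
  take <- function(iv) {
    if (iv[1L] <= iv[2L]) s[iv[1L]:iv[2L]] else c(s[iv[1L]:n], s[1L:iv[2L]])
  }
  rows <- list(
    data.frame(region = "LSC", length = partition$lsc_length, gc = gc_fraction(take(partition$lsc))),
    data.frame(region = "IRb", length = partition$ir_length, gc = gc_fraction(take(partition$irb))),
    data.frame(region = "SSC", length = partition$ssc_length, gc = gc_fraction(take(partition$ssc))),
    data.frame(region = "IRa", length = partition$ir_length, gc = gc_fraction(take(partition$ira))),
    data.frame(region = "total", length = n, gc = gc_fraction(s))
  )
  for (kind in c("CDS", "tRNA", "rRNA")) {
    feats <- Filter(function(f) f$kind == kind, record$features)
    if (!length(feats)) next
    idx <- unique(unlist(lapply(feats, function(f)
      unlist(apply(f$parts, 1L, function(p) seq.int(p[1L], p[2L]), simplify = FALSE)))))
    rows[[length(rows) + 1L]] <-
      data.frame(region = kind, length = length(idx), gc = gc_fraction(s[idx]))
  }
  out <- do.call(rbind, rows)
  zero <- out$length == 0L
  if (any(zero)) plast_warning("zero-length region: GC undefined")
  out
}

#' Gene content summary of a plastome
#'
#' Unique gene count is by name (IR duplicates are distinct features sharing a
#' name). A gene counts as IR-duplicated when at least two same-named copies
#' lie wholly inside the IRs.
#'
#' @param record a [plastome_record()]
#' @param partition the record's partition
#' @return list with `n_unique_genes`, `n_ir_duplicated`, `counts_by_kind`,
#'   `intron_genes` (data.frame name/introns) and `n_features`
#' @export
gene_content_summary <- function(record, partition = NULL) {
  feats <- Filter(function(f) f$kind != "pseudogene", record$features)
  if (!length(feats)) {
    return(list(n_unique_genes = 0L, n_ir_duplicated = 0L,
                counts_by_kind = c(CDS = 0L, tRNA = 0L, rRNA = 0L),
                intron_genes = data.frame(name = character(0), introns = integer(0)),
                n_features = 0L))
  }
  names_all <- vapply(feats, `[[`, "", "name")
  kinds <- vapply(feats, `[[`, "", "kind")
  uniq <- !duplicated(names_all)
  counts_by_kind <- c(CDS = sum(kinds[uniq] == "CDS"),
                      tRNA = sum(kinds[uniq] == "tRNA"),
                      rRNA = sum(kinds[uniq] == "rRNA"))
  n_ir_dup <- 0L
  if (!is.null(partition)) {
    in_ir <- vapply(feats, function(f) {
      all(structural_region_of(c(f$parts[, "start"], f$parts[, "end"]), partition) == "IR")
    }, logical(1))
    dup_names <- unique(names_all[duplicated(names_all)])
    n_ir_dup <- sum(vapply(dup_names, function(nm) {
      any(in_ir[names_all == nm])
    }, logical(1)))
  }
  introns <- vapply(feats, `[[`, 0L, "intron_count")
  with_introns <- uniq & introns > 0L
  list(
    n_unique_genes = sum(uniq),
    n_ir_duplicated = n_ir_dup,
    counts_by_kind = counts_by_kind,
    intron_genes = data.frame(name = names_all[with_introns],
                              introns = introns[with_introns],
                              stringsAsFactors = FALSE),
    n_features = length(feats)
  )
}

#' Compare IR junctions across accessions
#'
#' For each of the four junctions JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa)
#' and JLA (IRa/LSC), reports the gene overlapping or nearest to the junction
#' and the bases of that gene on each side of it. A same-named feature shorter
#' than the longest copy of that gene in the record is flagged as a pseudogene
#' fragment. Records whose partition is NULL (no IR found) are skipped with a
#' warning.
#'
#' @param records list of [plastome_record()]s
#' @param partitions list of matching partitions (NULL entries skipped)
#' @return data.frame keyed (accession, junction) with columns `gene`, `kind`,
#'   `side_before`, `side_after` (bp of the gene on the two sides of the
#'   junction; both > 0 for a spanning gene), `distance` (0 when overlapping)
#'   and `is_fragment`
#' @export
junction_report <- function(records, partitions) {
  stopifnot(length(records) == length(partitions))
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]; part <- partitions[[i]]
    if (is.null(part)) {
      plast_warning(sprintf("%s: no quadripartite partition; skipped", rec$accession))
      next
    }
    n <- rec$length
    junctions <- c(
      JLB = part$lsc[2L],  # boundary between this position and the next
      JSB = part$irb[2L],
      JSA = part$ssc[2L],
      JLA = part$ira[2L]
    )
    full_len <- vapply(rec$features, feature_length, 0L)
    max_len_by_name <- tapply(full_len, vapply(rec$features, `[[`, "", "name"), max)
    for (j in seq_along(junctions)) {
      jpos <- junctions[[j]]
      hit <- .nearest_feature(rec, jpos, n)
      if (is.null(hit)) next
      f <- rec$features[[hit$index]]
      rows[[length(rows) + 1L]] <- data.frame(
        accession = rec$accession,
        junction = names(junctions)[j],
        gene = f$name,
        kind = f$kind,
        side_before = hit$side_before,
        side_after = hit$side_after,
        distance = hit$distance,
        is_fragment = f$kind == "pseudogene" ||
          feature_length(f) < max_len_by_name[[f$name]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), junction = character(0),
                      gene = character(0), kind = character(0),
                      side_before = integer(0), side_after = integer(0),
                      distance = integer(0), is_fragment = logical(0))
  }
  rownames(out) <- NULL
  out
}

# Junction sits between position jpos and jpos + 1 (circular). For each
# feature, bases at positions <= jpos (within a local window) are
# "side_before", the rest "side_after"; overlap means distance 0.
#' @keywords internal
.nearest_feature <- function(rec, jpos, n) {
  if (!length(rec$features)) return(NULL)
  best <- NULL
  for (fi in seq_along(rec$features)) {
    f <- rec$features[[fi]]
    a <- min(f$parts[, "start"]); b <- max(f$parts[, "end"])
    if (f$wraps) { a <- f$parts[1L, "start"]; b <- f$parts[2L, "end"] }
    # circular signed distance from the feature to the junction boundary
    if (.pos_in(jpos, a, b, n) || .pos_in(((jpos) %% n) + 1L, a, b, n)) {
      len <- circ_length(a, b, n)
      before <- (jpos - a + 1L) %% n
      before <- min(max(before, 0L), len)
      if (!.pos_in(jpos, a, b, n)) before <- 0L
      d <- list(index = fi, distance = 0L,
                side_before = before, side_after = len - before)
    } else {
      gap_after <- (a - jpos - 1L) %% n   # junction ... feature start
      gap_before <- (jpos - b) %% n       # feature end ... junction
      d <- list(index = fi, distance = min(gap_after, gap_before),
                side_before = 0L, side_after = circ_length(a, b, n))
    }
    if (is.null(best) || d$distance < best$distance) best <- d
  }
  best
}

#' @keywords internal
.pos_in <- function(p, a, b, n) {
  if (a <= b) p >= a && p <= b else p >= a || p <= b
}

#' Write a quadripartite partition as BED
#'
#' BED intervals are 0-based half-open per the format; wrapping regions are
#' split into two BED lines.
#'
#' @param partition a [detect_partition()] result
#' @param accession sequence name for the BED chrom column
#' @param path output path
#' @return `path`, invisibly
#' @export
write_partition_bed <- function(partition, accession, path) {
  n <- partition$genome_length
  lines <- character(0)
  for (nm in c("lsc", "irb", "ssc", "ira")) {
    iv <- partition[[nm]]
    label <- toupper(nm)
    if (iv[1L] <= iv[2L]) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", accession, iv[1L] - 1L, iv[2L], label))
    } else {
      lines <- c(lines,
                 sprintf("%s\t%d\t%d\t%s", accession, iv[1L] - 1L, n, label),
                 sprintf("%s\t%d\t%d\t%s", accession, 0L, iv[2L], label))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
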