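# Variant extraction against a reference row, Ts/Tv classing, windowed and
# per-locus nucleotide diversity, hotspot ranking and pairwise p-distances.
# The diversity estimator is the average pairwise difference per usable site
# with pairwise deletion of gaps/N (DnaSP-like); no Jukes-Cantor correction
# is applied to pi or p-distances.

#' Classify substitutions as transition or transversion
#'
#' @param ref,alt vectors of bases
#' @return character vector over {"Ts","Tv"}
#' @export
classify_substitution <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  ts <- (ref %in% PURINES & alt %in% PURINES) |
    (ref %in% PYRIMIDINES & alt %in% PYRIMIDINES)
  ifelse(ts, "Ts", "Tv")
}

#' Call SNPs of a query accession against the alignment reference
#'
#' Every alignment column where both the reference and the query carry a base
#' (not gap or N) and the bases differ yields one SNP record; runs of adjacent
#' variant columns emit one record per column (multinucleotide variants are
#' counted per position). Structural and functional regions are attached via
#' reference coordinates when a partition / annotation of the reference
#' genome is supplied.
#'
#' @param aln a [plast_alignment()]
#' @param query query accession (returns an empty table when it equals the
#'   reference)
#' @param partition optional [detect_partition()] result for the reference
#' @param annotation optional [annotate_regions()] result for the reference
#' @return data.frame with columns accession, ref_pos, ref_allele,
#'   alt_allele, ts_tv, structural_region, functional_region, locus
#' @export
call_snps <- function(aln, query, partition = NULL, annotation = NULL) {
  empty <- data.frame(accession = character(0), ref_pos = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      ts_tv = character(0), structural_region = character(0),
                      functional_region = character(0), locus = character(0),
                      stringsAsFactors = FALSE)
  if (query == aln$reference_id) return(empty)
  r <- aln$matrix[aln$reference_id, ]
  q <- aln$matrix[query, ]
  usable <- is_base(r) & is_base(q)
  idx <- which(usable & r != q)
  if (!length(idx)) return(empty)
  pos <- aln$column_map[idx]
  out <- data.frame(
    accession = query,
    ref_pos = pos,
    ref_allele = r[idx],
    alt_allele = q[idx],
    ts_tv = classify_substitution(r[idx], q[idx]),
    structural_region = if (!is.null(partition)) structural_region_of(pos, partition) else NA_character_,
    functional_region = if (!is.null(annotation)) annotation$class[pos] else NA_character_,
    locus = if (!is.null(annotation)) annotation$locus[pos] else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Call indel events of a query accession against the alignment reference
#'
#' Each maximal run of gap characters present in exactly one of the two rows
#' is one event (length = run length). Columns gapped in both rows are
#' ignored entirely (they do not split an event). The event position is the
#' nearest preceding reference coordinate.
#'
#' @inheritParams call_snps
#' @return data.frame with columns accession, ref_pos, length, kind
#'   ("insertion"/"deletion" relative to the reference), structural_region,
#'   locus
#' @export
call_indels <- function(aln, query, partition = NULL, annotation = NULL) {
  empty <- data.frame(accession = character(0), ref_pos = integer(0),
                      length = integer(0), kind = character(0),
                      structural_region = character(0), locus = character(0),
                      stringsAsFactors = FALSE)
  if (query == aln$reference_id) return(empty)
  r <- aln$matrix[aln$reference_id, ]
  q <- aln$matrix[query, ]
  keep <- !(r == "-" & q == "-")
  r <- r[keep]; q <- q[keep]
  cmap <- aln$column_map[keep]
  state <- ifelse(q == "-", "del", ifelse(r == "-", "ins", "none"))
  rl <- rle(state)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ev <- which(rl$values != "none")
  if (!length(ev)) return(empty)
  # nearest reference coordinate at or before each event start
  last_ref <- cummax(ifelse(is.na(cmap), 0L, cmap))
  pos <- pmax(last_ref[starts[ev]], 1L)
  out <- data.frame(
    accession = query,
    ref_pos = pos,
    length = rl$lengths[ev],
    kind = ifelse(rl$values[ev] == "del", "deletion", "insertion"),
    structural_region = if (!is.null(partition)) structural_region_of(pos, partition) else NA_character_,
    locus = if (!is.null(annotation)) annotation$locus[pos] else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Pairwise difference/usable-site counts per column subset for all row pairs.
# Returns a list of matrices diffs, usable (pairs x columns kept as vectors
# of per-pair totals via the supplied aggregator).
#' @keywords internal
.pair_stats <- function(aln, cols = NULL, subset = NULL) {
  prs <- accession_pairs(aln, subset)
  m <- if (is.null(cols)) aln$matrix else aln$matrix[, cols, drop = FALSE]
  base <- is_base(m)
  list(pairs = prs, matrix = m, base = base)
}

#' Sliding-window nucleotide diversity
#'
#' Windows tile the alignment columns (default non-overlapping 100-column
#' windows). Per window, pi is the average over all row pairs of
#' differences / usable sites, a site being usable for a pair when both rows
#' carry A/C/G/T there; pairs without usable sites in a window are dropped
#' from the average, and a window with none is flagged NA.
#'
#' @param aln a [plast_alignment()] with at least two rows
#' @param window window size in alignment columns (default 100)
#' @param step step between window starts (default `window`)
#' @return data.frame with columns start, end (1-based closed column span),
#'   pi, usable_sites (columns usable in at least one pair)
#' @export
window_pi <- function(aln, window = 100L, step = window) {
  if (n_accessions(aln) < 2L) stop("window_pi needs at least 2 rows")
  nc <- n_columns(aln)
  prs <- accession_pairs(aln)
  np <- ncol(prs)
  starts <- seq.int(1L, nc, by = step)
  ends <- pmin(starts + window - 1L, nc)
  bnd <- c(starts[1L] - 1L, ends)  # cumulative-sum breakpoints

  diff_cum <- matrix(0, nrow = np, ncol = length(ends))
  use_cum <- matrix(0, nrow = np, ncol = length(ends))
  any_use <- logical(nc)
  base <- is_base(aln$matrix)
  for (p in seq_len(np)) {
    a <- aln$matrix[prs[1L, p], ]; b <- aln$matrix[prs[2L, p], ]
    u <- base[prs[1L, p], ] & base[prs[2L, p], ]
    d <- u & (a != b)
    any_use <- any_use | u
    cu <- cumsum(u); cd <- cumsum(d)
    use_cum[p, ] <- cu[ends] - c(0, cu)[starts]
    diff_cum[p, ] <- cd[ends] - c(0, cd)[starts]
  }
  pi <- vapply(seq_along(ends), function(w) {
    ok <- use_cum[, w] > 0
    if (!any(ok)) return(NA_real_)
    mean(diff_cum[ok, w] / use_cum[ok, w])
  }, numeric(1))
  cum_any <- cumsum(any_use)
  data.frame(start = starts, end = ends, pi = pi,
             usable_sites = cum_any[ends] - c(0, cum_any)[starts])
}

#' Nucleotide diversity over an arbitrary set of alignment columns
#'
#' Same estimator as [window_pi()] applied once to a column subset.
#'
#' @param aln a [plast_alignment()]
#' @param cols integer vector of alignment columns
#' @param subset optional accession subset
#' @return single numeric pi (NA when no pair has a usable site)
#' @export
column_pi <- function(aln, cols, subset = NULL) {
  prs <- accession_pairs(aln, subset)
  if (!ncol(prs)) return(NA_real_)
  vals <- numeric(0)
  for (p in seq_len(ncol(prs))) {
    a <- aln$matrix[prs[1L, p], cols]; b <- aln$matrix[prs[2L, p], cols]
    u <- is_base(a) & is_base(b)
    if (!any(u)) next
    vals <- c(vals, sum(a != b & u) / sum(u))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Per-locus nucleotide diversity and mutation accounting
#'
#' Loci (genes, introns, intergenic spacers) are taken from a region
#' annotation of the reference genome and mapped to alignment columns through
#' the reference coordinate map. For each locus the table reports pi (same
#' pairwise estimator), the number of distinct polymorphic columns, the
#' number of distinct indel events (pooled over accessions, deduplicated by
#' position/length/kind), the mutation count (polymorphic columns + indel
#' events, the Table 5 convention) and indel diversity (pairwise indel events
#' per aligned locus column, averaged over row pairs).
#'
#' @param aln a [plast_alignment()]
#' @param annotation [annotate_regions()] of the reference genome
#' @return data.frame with columns locus, class, length (alignment columns
#'   spanned), pi, n_snp_columns, n_indel_events, n_mutations,
#'   indel_diversity; attribute `class_means` holds the unweighted per-class
#'   mean pi
#' @export
locus_pi <- function(aln, annotation) {
  loci <- locus_table(annotation)
  prs <- accession_pairs(aln)
  base <- is_base(aln$matrix)
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    cols <- aln$ref_column[loci$start[i]:loci$end[i]]
    # include reference-gap (insertion) columns interior to the locus span
    cols <- seq.int(min(cols), max(cols))
    sub <- aln$matrix[, cols, drop = FALSE]
    bsub <- base[, cols, drop = FALSE]
    vals <- numeric(0)
    indel_pair <- numeric(0)
    poly <- logical(length(cols))
    for (p in seq_len(ncol(prs))) {
      a <- sub[prs[1L, p], ]; b <- sub[prs[2L, p], ]
      u <- bsub[prs[1L, p], ] & bsub[prs[2L, p], ]
      if (any(u)) vals <- c(vals, sum(a != b & u) / sum(u))
      poly <- poly | (u & a != b)
      # pairwise indel events: gap runs in exactly one row
      keep <- !(a == "-" & b == "-")
      st <- ifelse(a[keep] == "-", "a", ifelse(b[keep] == "-", "b", "n"))
      rl <- rle(st)
      indel_pair <- c(indel_pair, sum(rl$values != "n"))
    }
    ev <- .locus_indel_events(sub)
    rows[[i]] <- data.frame(
      locus = loci$locus[i], class = loci$class[i], length = length(cols),
      pi = if (length(vals)) mean(vals) else NA_real_,
      n_snp_columns = sum(poly),
      n_indel_events = ev,
      n_mutations = sum(poly) + ev,
      indel_diversity = if (length(indel_pair)) mean(indel_pair) / length(cols) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  defined <- !is.na(out$pi)
  cm <- tapply(out$pi[defined], out$class[defined], mean)
  attr(out, "class_means") <- cm
  out
}

# Distinct indel events within a locus sub-alignment: per non-reference row,
# gap runs against the first row, deduplicated by (start, length, kind).
#' @keywords internal
.locus_indel_events <- function(sub) {
  ref <- sub[1L, ]
  keys <- character(0)
  for (r in seq_len(nrow(sub))[-1L]) {
    q <- sub[r, ]
    keep <- !(ref == "-" & q == "-")
    if (!any(keep)) next
    idx <- which(keep)
    st <- ifelse(q[keep] == "-", "del", ifelse(ref[keep] == "-", "ins", "n"))
    rl <- rle(st)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    ev <- which(rl$values != "n")
    if (length(ev)) {
      keys <- c(keys, paste(idx[starts[ev]], rl$lengths[ev], rl$values[ev]))
    }
  }
  length(unique(keys))
}

#' Rank mutational hotspots
#'
#' Loci sorted by pi descending (ties broken by mutation count then name);
#' the top k form the hotspot table.
#'
#' @param locus_tab data.frame from [locus_pi()]
#' @param k number of hotspots to keep (default 20; the whole table when
#'   fewer loci exist)
#' @return the top-k rows of the locus table
#' @export
rank_hotspots <- function(locus_tab, k = 20L) {
  tab <- locus_tab[!is.na(locus_tab$pi), , drop = FALSE]
  ord <- order(-tab$pi, -tab$n_mutations, tab$locus)
  out <- tab[ord, , drop = FALSE][seq_len(min(k, nrow(tab))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise p-distance matrix
#'
#' p = differences / usable sites for each accession pair (pairwise deletion
#' of gaps and Ns; raw proportion, no correction).
#'
#' @param aln a [plast_alignment()]
#' @param subset optional accession subset
#' @return symmetric numeric matrix with zero diagonal
#' @export
pairwise_p_distance <- function(aln, subset = NULL) {
  acc <- if (is.null(subset)) rownames(aln$matrix) else subset
  k <- length(acc)
  out <- matrix(0, k, k, dimnames = list(acc, acc))
  base <- is_base(aln$matrix)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      a <- aln$matrix[acc[i], ]; b <- aln$matrix[acc[j], ]
      u <- base[acc[i], ] & base[acc[j], ]
      out[i, j] <- out[j, i] <-
        if (any(u)) sum(a != b & u) / sum(u) else NA_real_
    }
  }
  out
}

#' Intraspecific diversity per species
#'
#' Mean pairwise p-distance over the accession pairs of each species with
#' more than one accession.
#'
#' @param aln a [plast_alignment()]
#' @return data.frame with columns species, n_accessions, mean_p
#' @export
intraspecific_diversity <- function(aln) {
  pd <- pairwise_p_distance(aln)
  species <- unique(aln$species)
  rows <- lapply(species, function(sp) {
    acc <- accessions_of(aln, sp)
    if (length(acc) < 2L) return(NULL)
    prs <- utils::combn(acc, 2L)
    data.frame(species = sp, n_accessions = length(acc),
               mean_p = mean(pd[cbind(prs[1L, ], prs[2L, ])]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(0), n_accessions = integer(0),
                      mean_p = numeric(0))
  }
  out
}
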