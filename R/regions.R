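# Per-position functional region classing: every position of a plastome is
# exactly one of CDS (gene exon, including tRNA/rRNA exons), intron, or IGS.
# Intergenic spacers are named "upstreamGene-downstreamGene" in forward-strand
# order (e.g. "infA-rps8").

#' Annotate functional regions of a plastome
#'
#' Exonic parts of CDS/tRNA/rRNA features are classed `CDS` (gene region);
#' gaps between parts of one feature are classed `intron`; everything else is
#' `IGS`. When features overlap, precedence is CDS > tRNA/rRNA > pseudogene
#' (a warning reports the overlap). Spacer runs are named after their flanking
#' genes in forward-strand coordinate order; spacers at the linearization ends
#' wrap around the circle.
#'
#' @param record a [plastome_record()]
#' @return an object of class `region_annotation`: list with `class`
#'   (character vector, one of CDS/intron/IGS per position), `locus`
#'   (character vector of locus names per position), and `loci` (data.frame of
#'   contiguous locus intervals with columns locus, class, start, end)
#' @export
annotate_regions <- function(record) {
  n <- record$length
  cls <- rep("IGS", n)
  locus <- rep(NA_character_, n)

  precedence <- c(pseudogene = 1L, tRNA = 2L, rRNA = 2L, CDS = 3L)
  feats <- record$features
  if (length(feats)) {
    ord <- order(vapply(feats, function(f) precedence[[f$kind]], integer(1)))
    overlapped <- FALSE
    rank <- integer(n)  # precedence already painted at each position
    for (f in feats[ord]) {
      pr <- precedence[[f$kind]]
      exon_idx <- unlist(apply(f$parts, 1L, function(p) seq.int(p[1L], p[2L]),
                               simplify = FALSE))
      if (any(rank[exon_idx] >= pr & cls[exon_idx] != "IGS")) overlapped <- TRUE
      paint <- rank[exon_idx] <= pr
      exon_idx <- exon_idx[paint]
      cls[exon_idx] <- "CDS"
      locus[exon_idx] <- f$name
      rank[exon_idx] <- pr
      if (nrow(f$parts) > 1L && !f$wraps) {
        for (i in seq_len(nrow(f$parts) - 1L)) {
          gap <- seq.int(f$parts[i, "end"] + 1L, f$parts[i + 1L, "start"] - 1L)
          gap <- gap[rank[gap] < pr]
          if (length(gap)) {
            cls[gap] <- "intron"
            locus[gap] <- f$name
            rank[gap] <- pr
          }
        }
      }
    }
    if (overlapped)
      plast_warning("overlapping features resolved by precedence CDS > tRNA/rRNA > pseudogene")
  }

  # name IGS runs after flanking genes in forward order (circular at the ends)
  igs <- cls == "IGS"
  if (any(igs)) {
    runs <- true_runs(igs)
    gene_at <- function(pos) if (is.na(locus[pos])) "END" else locus[pos]
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, "start"]; b <- runs[i, "end"]
      up <- if (a > 1L) gene_at(a - 1L) else gene_at(if (b < n) n else a)  # wrap
      down <- if (b < n) gene_at(b + 1L) else gene_at(if (a > 1L) 1L else b)
      nm <- if (all(igs)) "IGS" else paste0(up, "-", down)
      locus[a:b] <- nm
    }
  }

  # contiguous locus intervals
  key <- paste(cls, locus, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  loci <- data.frame(
    locus = locus[starts],
    class = cls[starts],
    start = starts,
    end = ends,
    stringsAsFactors = FALSE
  )

  structure(list(class = cls, locus = locus, loci = loci, length = n),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<region_annotation> %s bp: %s\n",
              format(x$length, big.mark = ","),
              paste(sprintf("%s %s", names(tab), format(as.integer(tab), big.mark = ",")),
                    collapse = ", ")))
  invisible(x)
}

#' Base counts per functional class
#' @param annotation a [annotate_regions()] result
#' @return named integer vector over CDS/intron/IGS
#' @export
region_class_counts <- function(annotation) {
  out <- c(CDS = 0L, intron = 0L, IGS = 0L)
  tab <- table(annotation$class)
  out[names(tab)] <- as.integer(tab)
  out
}

# Loci merged across intervals: one row per (locus, class) with total length
# and the covering column span on the annotated genome.
#' @keywords internal
locus_table <- function(annotation) {
  li <- annotation$loci
  key <- paste(li$locus, li$class, sep = "\r")
  agg <- lapply(split(seq_len(nrow(li)), key), function(idx) {
    data.frame(locus = li$locus[idx[1L]], class = li$class[idx[1L]],
               start = min(li$start[idx]), end = max(li$end[idx]),
               bases = sum(li$end[idx] - li$start[idx] + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
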