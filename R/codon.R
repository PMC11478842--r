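# Codon usage (RSCU), amino-acid composition, and Nei-Gojobori (1986) Ka/Ks
# with selection classing. The genetic code is the bacterial/plastid table 11
# throughout (Biostrings::getGeneticCode("11")).

#' @keywords internal
.genetic_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

#' @keywords internal
.all_codons <- function() {
  b <- DNA_BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# amino-acid physicochemical groups (fixed convention, see vignette)
.AA_GROUPS <- list(
  hydrophobic = c("A", "V", "L", "I", "P", "F", "M", "W"),
  hydrophilic = c("S", "T", "C", "N", "Q", "Y"),
  acidic = c("D", "E"),
  basic = c("K", "R", "H"),
  neutral = c("G")
)

#' @keywords internal
.split_codons <- function(cds, label = "CDS") {
  cds <- toupper(cds)
  extra <- nchar(cds) %% 3L
  if (extra) {
    plast_warning(sprintf("%s length %d not divisible by 3; trailing %d base(s) trimmed",
                          label, nchar(cds), extra))
    cds <- substr(cds, 1L, nchar(cds) - extra)
  }
  if (!nchar(cds)) return(character(0))
  starts <- seq.int(1L, nchar(cds), by = 3L)
  substring(cds, starts, starts + 2L)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = observed count of codon c divided by the expected count under
#' uniform usage within its synonymous family (family counts / degeneracy).
#' Stop codons form their own family. Codons containing N are skipped;
#' internal stop codons are counted with a warning. Third-codon-position base
#' composition is attached (plastome CDSs shift toward A/T there).
#'
#' @param cds_sequences character vector (or list) of CDS sequences
#' @param genetic_code ignored placeholder for the fixed plastid table 11
#' @return list with `rscu` (data.frame codon/amino_acid/count/rscu),
#'   `third_position` (named base-fraction vector) and `n_codons`
#' @export
rscu <- function(cds_sequences, genetic_code = 11L) {
  code <- .genetic_code()
  codons <- unlist(lapply(seq_along(cds_sequences), function(i)
    .split_codons(cds_sequences[[i]], label = paste0("CDS ", i))))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  if (!length(codons)) stop("no complete codons supplied")
  counts <- table(factor(codons, levels = .all_codons()))
  aa <- code[.all_codons()]
  n_internal_stop <- sum(aa[codons[-length(codons)]] == "*")
  if (n_internal_stop > 0L)
    plast_warning(sprintf("%d internal stop codon(s) counted", n_internal_stop))
  fam_total <- tapply(as.integer(counts), aa, sum)[aa]
  degeneracy <- table(aa)[aa]
  vals <- ifelse(fam_total > 0, as.integer(counts) / (fam_total / as.integer(degeneracy)), NA_real_)
  third <- substring(codons, 3L, 3L)
  third_comp <- table(factor(third, levels = DNA_BASES)) / length(third)
  list(
    rscu = data.frame(codon = .all_codons(), amino_acid = unname(aa),
                      count = as.integer(counts), rscu = unname(vals),
                      stringsAsFactors = FALSE),
    third_position = c(third_comp),
    n_codons = length(codons)
  )
}

#' Amino-acid frequencies and physicochemical group fractions
#'
#' Translates the supplied CDSs under the plastid code and reports per-amino
#' acid frequencies (stops excluded) and the fractions falling in a fixed
#' hydropathy/charge grouping (hydrophobic, hydrophilic, acidic, basic,
#' neutral).
#'
#' @inheritParams rscu
#' @return list with `frequencies` (named, sums to 1) and `groups` (named,
#'   sums to 1)
#' @export
amino_acid_profile <- function(cds_sequences) {
  if (!length(cds_sequences)) stop("no CDS sequences supplied")
  code <- .genetic_code()
  codons <- unlist(lapply(cds_sequences, .split_codons))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  aa <- code[codons]
  aa <- aa[aa != "*"]
  if (!length(aa)) stop("no translatable codons supplied")
  freq <- table(factor(aa, levels = sort(unique(unname(code[code != "*"]))))) / length(aa)
  groups <- vapply(.AA_GROUPS, function(g) sum(freq[g], na.rm = TRUE), numeric(1))
  list(frequencies = c(freq), groups = groups)
}

# --- Nei-Gojobori 1986 -------------------------------------------------------

# Per-codon synonymous site count: at each position, the fraction of the 3
# possible changes that are synonymous. Changes to stop codons count as
# nonsynonymous; stop codons themselves are excluded by the caller.
#' @keywords internal
.ng86_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- .genetic_code()
    syn <- stats::setNames(numeric(64L), .all_codons())
    for (cod in .all_codons()) {
      if (code[[cod]] == "*") { syn[[cod]] <- NA_real_; next }
      total <- 0
      for (pos in 1:3) {
        for (b in setdiff(DNA_BASES, substr(cod, pos, pos))) {
          alt <- cod
          substr(alt, pos, pos) <- b
          if (code[[alt]] != "*" && code[[alt]] == code[[cod]]) total <- total + 1 / 3
        }
      }
      syn[[cod]] <- total
    }
    cache <<- syn
    cache
  }
})

# Average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways (unweighted); pathways passing through a stop
# codon are excluded (all pathways used if every one is blocked).
#' @keywords internal
.ng86_diffs <- local({
  cache <- new.env(parent = emptyenv())
  function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    code <- .genetic_code()
    pos <- which(seq_chars(c1) != seq_chars(c2))
    if (!length(pos)) return(c(syn = 0, nonsyn = 0))
    perms <- .permutations(pos)
    paths <- matrix(NA_real_, nrow = nrow(perms), ncol = 2L)
    for (p in seq_len(nrow(perms))) {
      cur <- c1
      sd <- 0; nd <- 0
      blocked <- FALSE
      for (step in perms[p, ]) {
        nxt <- cur
        substr(nxt, step, step) <- substr(c2, step, step)
        if (code[[nxt]] == "*") { blocked <- TRUE }
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths[p, ] <- c(sd, nd)
      if (blocked) paths[p, ] <- c(NA, NA)
    }
    ok <- !is.na(paths[, 1L])
    if (!any(ok)) ok <- rep(TRUE, nrow(paths))
    # blocked paths were overwritten with NA; recompute for the fallback case
    if (anyNA(paths[ok, ])) {
      for (p in which(is.na(paths[, 1L]))) {
        cur <- c1
        sd <- 0; nd <- 0
        for (step in perms[p, ]) {
          nxt <- cur
          substr(nxt, step, step) <- substr(c2, step, step)
          if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        paths[p, ] <- c(sd, nd)
      }
    }
    out <- c(syn = mean(paths[ok, 1L]), nonsyn = mean(paths[ok, 2L]))
    cache[[key]] <- out
    out
  }
})

#' @keywords internal
.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned sequence pair
#'
#' Synonymous site fractions per codon are averaged over the two sequences;
#' observed synonymous/nonsynonymous differences are averaged over all
#' minimal mutational pathways per codon (pathways through stop codons
#' excluded). The Jukes-Cantor correction is applied to both proportions:
#' d = -3/4 log(1 - 4p/3). Codons containing gaps or Ns in either sequence,
#' and stop codons, are skipped.
#'
#' @param cds1,cds2 aligned CDS strings of equal length (gaps in multiples of
#'   3 expected; any codon containing a gap is skipped)
#' @param gene optional gene label carried into the result
#' @return object of class `kaks_result`: list with gene, Ka, Ks, ratio
#'   (NA when Ks is 0), selection_class, and the underlying counts (S, N, Sd,
#'   Nd, pS, pN, n_codons)
#' @export
kaks_ng86 <- function(cds1, cds2, gene = NA_character_) {
  if (nchar(cds1) != nchar(cds2)) stop("aligned CDS pair must have equal length")
  code <- .genetic_code()
  sites <- .ng86_sites()
  cod1 <- .split_codons(cds1, "CDS 1")
  cod2 <- .split_codons(cds2, "CDS 2")
  ok <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2)
  ok[ok] <- code[cod1[ok]] != "*" & code[cod2[ok]] != "*"
  cod1 <- cod1[ok]; cod2 <- cod2[ok]
  if (!length(cod1)) stop("no comparable codons in the pair")
  S <- mean(c(sum(sites[cod1]), sum(sites[cod2])))
  N <- 3 * length(cod1) - S
  Sd <- 0; Nd <- 0
  differ <- which(cod1 != cod2)
  for (i in differ) {
    d <- .ng86_diffs(cod1[i], cod2[i])
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS)
  Ka <- jc(pN)
  if (anyNA(c(Ka, Ks)))
    plast_warning(sprintf("gene %s: proportion >= 3/4, Jukes-Cantor correction undefined", gene))
  cls <- classify_selection(Ka, Ks)
  structure(list(gene = gene, Ka = Ka, Ks = Ks,
                 ratio = if (!anyNA(c(Ka, Ks)) && Ks > 0) Ka / Ks else NA_real_,
                 selection_class = cls,
                 S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 n_codons = length(cod1)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %s: Ka %.4f / Ks %.4f = %s (%s)\n",
              x$gene, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$selection_class))
  invisible(x)
}

#' Classify selection from Ka and Ks
#'
#' Ka/Ks > 1 is positive, = 1 neutral, < 1 purifying selection. Ks = 0 with
#' Ka > 0 is classed positive (logged convention); Ka = Ks = 0 is undefined.
#'
#' @param ka,ks nonsynonymous / synonymous distances
#' @param tol equality tolerance for the neutral class
#' @return one of "positive", "neutral", "purifying", "undefined"
#' @export
classify_selection <- function(ka, ks, tol = 1e-9) {
  if (anyNA(c(ka, ks))) return("undefined")
  if (ks <= tol && ka <= tol) return("undefined")
  if (ks <= tol) return("positive")
  ratio <- ka / ks
  if (ratio > 1 + tol) "positive"
  else if (abs(ratio - 1) <= tol) "neutral"
  else "purifying"
}

#' Per-gene Ka/Ks table between a reference and a query accession
#'
#' Extracts each CDS gene of the reference record from the whole-genome
#' alignment (columns of its exonic parts), removes columns gapped in either
#' row, trims to whole codons and runs [kaks_ng86()]. Genes are deduplicated
#' by name (first copy used); minus-strand genes are reverse-complemented
#' into coding orientation.
#'
#' @param aln a [plast_alignment()] (reference row = reference genome)
#' @param query query accession
#' @param record the reference [plastome_record()] (source of CDS features)
#' @return data.frame with one row per gene: gene, Ka, Ks, ratio,
#'   selection_class, n_codons
#' @export
kaks_table <- function(aln, query, record) {
  feats <- Filter(function(f) f$kind == "CDS", record$features)
  nm <- vapply(feats, `[[`, "", "name")
  feats <- feats[!duplicated(nm)]
  rows <- lapply(feats, function(f) {
    cols <- unlist(apply(f$parts, 1L, function(p)
      aln$ref_column[seq.int(p[1L], p[2L])], simplify = FALSE))
    a <- aln$matrix[aln$reference_id, cols]
    b <- aln$matrix[query, cols]
    keep <- a != "-" & b != "-"
    a <- a[keep]; b <- b[keep]
    trim <- length(a) %% 3L
    if (trim) { a <- a[seq_len(length(a) - trim)]; b <- b[seq_len(length(b) - trim)] }
    if (!length(a)) return(NULL)
    s1 <- chars_seq(a); s2 <- chars_seq(b)
    if (f$strand == "-") { s1 <- revcomp(s1); s2 <- revcomp(s2) }
    res <- suppressWarnings(kaks_ng86(s1, s2, gene = f$name))
    data.frame(gene = f$name, Ka = res$Ka, Ks = res$Ks, ratio = res$ratio,
               selection_class = res$selection_class, n_codons = res$n_codons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), Ka = numeric(0), Ks = numeric(0),
                      ratio = numeric(0), selection_class = character(0),
                      n_codons = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Mean Ka/Ks over a gene table
#'
#' Unweighted mean of the per-gene defined ratios; genes whose ratio is
#' undefined (Ks = 0 or failed correction) are excluded.
#'
#' @param tab data.frame from [kaks_table()]
#' @return numeric mean (NA when no gene has a defined ratio)
#' @export
mean_kaks <- function(tab) {
  ok <- !is.na(tab$ratio)
  if (!any(ok)) return(NA_real_)
  mean(tab$ratio[ok])
}
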