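# Plastome family simulator: an ancestral quadripartite genome evolved along
# a phylogeny with region-heterogeneous substitution (LSC/SSC >> IR,
# Kimura-style Ts:Tv kernel), indels, SSR slippage, planted species-
# diagnostic SNPs with conserved flanks, and an optional IR-expansion event
# that captures former SSC genes -- with machine-readable truth tables so
# every downstream stage is testable without external data.
#
# The ancestor is generated on a reduced frame (LSC + IRb + SSC); full
# genomes append IRa = revcomp(IRb), so IR mutations are concerted by
# construction and the true multiple alignment is exact (evolution happens on
# the alignment; no realignment step).

.LSC_GENES <- c("psbA", "matK", "rps16", "trnK-UUU", "psbK", "atpA", "atpF",
                "atpH", "atpI", "rps2", "rpoB", "trnC-GCA", "petN", "psbM",
                "psbD", "psbC", "psaB", "psaA", "ycf3", "rps4", "ndhJ", "ndhK",
                "ndhC", "atpE", "atpB", "rbcL", "accD", "psaI", "ycf4", "cemA",
                "petA", "psbJ", "psbL", "psbF", "psbE", "petL", "petG", "psaJ",
                "rpl33", "rps18", "rpl20", "rps12", "clpP", "psbB", "psbT",
                "psbN", "psbH", "petB", "petD", "rpoA", "rps11", "rpl36",
                "infA", "rps8", "rpl14", "rpl16", "rps3", "rpl22")
.IR_GENES <- c("rpl2", "rpl23", "ycf2", "ndhB", "rrn16", "trnI-GAU",
               "trnA-UGC", "rrn23", "rrn4.5", "rrn5")
.SSC_GENES <- c("rpl32", "trnL-UAG", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
                "ndhI", "ndhA", "ndhH", "rps15")
.INTRON_GENES <- c("rps16", "atpF", "rpoC1", "clpP", "petB", "petD", "rpl16",
                   "rpl2", "ndhB", "ndhA", "ycf3")

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_OPTIONS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Simulation configuration
#'
#' Defaults state the emulated world: a 150 kb quadripartite plastome
#' (LSC 83 kb, IR 25 kb, SSC 17 kb) at 38% GC, six accessions of five
#' species (two of the target, Plantago lanceolata; Plantago ovata as the
#' reference) related by a fixed tree with plastome-scale branch lengths, IR
#' mutation rate one tenth of the single-copy regions, Ts:Tv 1.2, indel
#' events at 0.15 per substitution with geometric lengths (mean 8), ten
#' planted microsatellite loci with slippage, twelve planted diagnostic SNPs
#' (two spaced for a ~1.8 kb amplicon in the rpoC2 / rpoC2-rpoC1 region) and
#' a 9 kb IR expansion in the Plantago maritima accession.
#'
#' @param seed RNG seed for [simulate_plastome_family()]
#' @param lsc_length,ir_length,ssc_length region sizes in bp
#' @param gc ancestral GC content
#' @param tree newick string, branch lengths in expected substitutions/site
#'   (before region scaling); tip labels are accessions
#' @param species named character vector accession -> species
#' @param reference_id reference accession (background species)
#' @param rate_multipliers named multipliers for LSC/SSC/IR
#' @param ts_tv transition:transversion ratio of the mutation kernel
#' @param indel_rate indel events per substitution
#' @param indel_mean_len mean of the geometric indel length distribution
#' @param n_ssr number of planted SSR loci
#' @param ssr_slip_prob per-accession probability of one-unit slippage
#' @param diagnostic list(species, n, pair_spacing): planted diagnostic SNPs
#' @param ir_expansion NULL or list(accession, bp): IR expansion event
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
                              lsc_length = 83000L, ir_length = 25000L,
                              ssc_length = 17000L, gc = 0.38,
                              tree = NULL, species = NULL,
                              reference_id = "POVA1",
                              rate_multipliers = c(LSC = 1, SSC = 1, IR = 0.1),
                              ts_tv = 1.2,
                              indel_rate = 0.15, indel_mean_len = 8,
                              n_ssr = 10L, ssr_slip_prob = 0.3,
                              diagnostic = list(species = "Plantago lanceolata",
                                                n = 12L, pair_spacing = 1760L),
                              ir_expansion = list(accession = "PMAR1", bp = 9000L)) {
  if (is.null(tree)) {
    tree <- paste0("((((PLAN1:0.001,PLAN2:0.001):0.004,",
                   "(PARG1:0.003,PATR1:0.003):0.002):0.010,",
                   "PMAR1:0.015):0.010,POVA1:0.025);")
  }
  if (is.null(species)) {
    species <- c(PLAN1 = "Plantago lanceolata", PLAN2 = "Plantago lanceolata",
                 PARG1 = "Plantago argentea", PATR1 = "Plantago atrata",
                 PMAR1 = "Plantago maritima", POVA1 = "Plantago ovata")
  }
  stopifnot(2L * ir_length < lsc_length + 2L * ir_length + ssc_length,
            all(rate_multipliers >= 0), indel_rate >= 0)
  structure(list(
    seed = seed, lsc_length = lsc_length, ir_length = ir_length,
    ssc_length = ssc_length, gc = gc, tree = tree, species = species,
    reference_id = reference_id, rate_multipliers = rate_multipliers,
    ts_tv = ts_tv, indel_rate = indel_rate, indel_mean_len = indel_mean_len,
    n_ssr = n_ssr, ssr_slip_prob = ssr_slip_prob, diagnostic = diagnostic,
    ir_expansion = ir_expansion
  ), class = "simulation_config")
}

#' @keywords internal
.rand_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# place genes left to right in [from, to]; returns feature list (reduced coords)
#' @keywords internal
.place_genes <- function(names, from, to, min_gap = 120L) {
  feats <- list()
  pos <- from
  for (nm in names) {
    gap <- sample(seq.int(min_gap, min_gap + 280L), 1L)
    len <- if (startsWith(nm, "trn")) sample(70:90, 1L)
      else if (startsWith(nm, "rrn")) sample(c(1500L, 2900L, 120L, 100L), 1L)
      else 3L * sample(120:500, 1L)
    start <- pos + gap
    if (start + len - 1L > to) break
    kind <- if (startsWith(nm, "trn")) "tRNA" else if (startsWith(nm, "rrn")) "rRNA" else "CDS"
    strand <- sample(c("+", "-"), 1L)
    if (kind == "CDS" && nm %in% .INTRON_GENES) {
      e1 <- max(30L, round(len * 0.4)); intr <- max(60L, round(len * 0.25))
      e2 <- len - e1 - intr
      if (e2 >= 30L) {
        parts <- rbind(c(start, start + e1 - 1L),
                       c(start + e1 + intr, start + len - 1L))
        feats[[length(feats) + 1L]] <- gene_feature(nm, kind, strand, parts)
        pos <- start + len - 1L
        next
      }
    }
    feats[[length(feats) + 1L]] <-
      gene_feature(nm, kind, strand, cbind(start, start + len - 1L))
    pos <- start + len - 1L
  }
  feats
}

#' Simulate the ancestral plastome
#'
#' Random sequence at the configured GC, genes placed non-overlapping from a
#' real plastid gene inventory (rps19 spanning the LSC/IRb junction, ycf1
#' spanning SSC/IRa, an ndh gene cluster in the SSC tail for the expansion
#' event, rpoC2/rpoC1 flanking the marker region in the LSC), planted SSR
#' loci in intergenic spacers, diagnostic SNP positions reserved with
#' mutation-masked flanks, IRa an exact reverse complement of IRb, and IR
#' boundaries made exactly maximal. Consumes the RNG stream of the caller
#' (see [simulate_plastome_family()] for the seeded entry point).
#'
#' @param config a [simulation_config()]
#' @return the ancestor as a [plastome_record()]; attribute `layout` carries
#'   the generation-side truth used by [evolve()]
#' @export
simulate_ancestor <- function(config) {
  L <- config$lsc_length; I <- config$ir_length; S <- config$ssc_length
  R <- L + I + S
  s <- .rand_dna(R, config$gc)

  region <- c(rep("LSC", L), rep("IR", I), rep("SSC", S))
  rate <- unname(config$rate_multipliers[region])
  mask <- logical(R)

  # --- genes on the reduced frame ------------------------------------------
  pair_spacing <- config$diagnostic$pair_spacing
  rpoC2_len <- 3L * max(600L, ceiling((pair_spacing %/% 2L) / 3L))
  rpoC2_start <- 801L
  rpoC2 <- gene_feature("rpoC2", "CDS", "+",
                        cbind(rpoC2_start, rpoC2_start + rpoC2_len - 1L))
  rpoC1_start <- rpoC2_start + rpoC2_len + pair_spacing
  rpoC1_len <- 3L * 450L
  i1 <- round(rpoC1_len * 0.4)
  rpoC1 <- gene_feature("rpoC1", "CDS", "+",
                        rbind(c(rpoC1_start, rpoC1_start + i1 - 1L),
                              c(rpoC1_start + i1 + 200L,
                                rpoC1_start + rpoC1_len + 199L)))
  rps19_len <- 279L; rps19_overhang <- 60L
  rps19 <- gene_feature("rps19", "CDS", "-",
                        cbind(L - (rps19_len - rps19_overhang) + 1L,
                              L + rps19_overhang))
  feats <- c(list(rpoC2, rpoC1),
             .place_genes(.LSC_GENES, rpoC1_start + rpoC1_len + 400L,
                          L - rps19_len - 300L),
             list(rps19),
             .place_genes(.IR_GENES, L + rps19_overhang + 200L, L + I - 400L),
             .place_genes("ndhF", L + I + 100L, L + I + 2600L))
  # SSC tail cluster (expansion candidates) and junction-spanning ycf1
  ycf1_red <- 1299L; ycf1_ext <- 500L
  tail_from <- max(L + I + 2800L, R - max(3L * ycf1_red, S %/% 2L) - 4000L)
  feats <- c(feats,
             .place_genes(.SSC_GENES, tail_from, R - ycf1_red - 200L),
             list(gene_feature("ycf1", "CDS", "+", cbind(R - ycf1_red + 1L, R))))

  gene_idx <- unlist(lapply(feats, function(f)
    unlist(apply(f$parts, 1L, function(p) seq.int(p[1L], p[2L]), simplify = FALSE))))
  gene_mask <- logical(R); gene_mask[gene_idx] <- TRUE

  # --- junction masks and maximal IR boundaries ----------------------------
  jmask <- c(1:3, (L - 2L):(L + 3L), (L + I - 2L):(L + I + 3L), (R - 2L):R)
  mask[jmask] <- TRUE
  # make planted IR boundaries exactly maximal: the base just outside each
  # junction must not complement-match its anti-diagonal partner (all
  # partners jointly, since one base may face several boundary variants)
  block_pairs <- function(i, js) {
    while (any(s[i] == .COMPLEMENT[s[js]])) s[i] <<- sample(DNA_BASES, 1L)
  }
  block_pairs(L, 1L)

  # --- IR expansion boundary (snapped into intergenic sequence) ------------
  exp_bp <- NA_integer_
  jsb_partners <- R
  if (!is.null(config$ir_expansion)) {
    e0 <- config$ir_expansion$bp
    stopifnot(e0 < S - 400L)
    while (any(gene_mask[pmax(1L, (R - e0 - 3L)):(R - e0 + 3L)]) && e0 < S - 400L)
      e0 <- e0 + 1L
    exp_bp <- e0
    mask[(R - e0 - 2L):(R - e0 + 3L)] <- TRUE
    jsb_partners <- c(jsb_partners, R - e0)
  }
  block_pairs(L + I + 1L, jsb_partners)

  # --- diagnostic SNP positions (conserved, mutation-masked flanks) --------
  diag_flank <- 30L
  marker_a <- rpoC2_start + rpoC2_len - 301L            # inside rpoC2 CDS
  marker_b <- marker_a + pair_spacing                   # inside rpoC2-rpoC1 IGS
  stopifnot(marker_b < rpoC1_start - 50L)
  n_extra <- max(0L, config$diagnostic$n - 2L)
  lsc_igs <- which(!gene_mask[1:L])
  lsc_igs <- lsc_igs[lsc_igs > 200L & lsc_igs < L - 400L]
  extra <- integer(0)
  cand <- setdiff(lsc_igs, unlist(lapply(c(marker_a, marker_b), function(p)
    (p - 2L * diag_flank):(p + 2L * diag_flank))))
  while (length(extra) < n_extra && length(cand)) {
    p <- sample(cand, 1L)
    extra <- c(extra, p)
    cand <- setdiff(cand, (p - 2L * diag_flank):(p + 2L * diag_flank))
  }
  diag_pos <- sort(c(marker_a, marker_b, extra))
  diag <- data.frame(pos = diag_pos, ancestral = s[diag_pos],
                     target_allele = unname(.TS_PARTNER[s[diag_pos]]),
                     stringsAsFactors = FALSE)
  for (p in diag_pos) mask[max(1L, p - diag_flank):min(R, p + diag_flank)] <- TRUE

  # --- planted SSR loci in intergenic sequence -----------------------------
  ssr_pool <- list(c("A", 9L), c("T", 10L), c("A", 12L), c("AT", 6L),
                   c("TA", 5L), c("AAT", 5L), c("ATT", 4L), c("AATC", 4L),
                   c("AT", 7L), c("TTA", 5L), c("A", 8L), c("TTG", 4L))
  free <- which(!gene_mask & !mask & region != "IR")
  ssr_rows <- list()
  for (k in seq_len(min(config$n_ssr, length(ssr_pool)))) {
    unit <- ssr_pool[[k]][1L]; copies <- as.integer(ssr_pool[[k]][2L])
    span <- nchar(unit) * copies
    ok <- free[free + span + 2L <= R]
    if (length(ok) > 400L) ok <- sort(sample(ok, 400L))
    # choose a start whose whole span (plus one flanking base each side) is free
    good <- ok[vapply(ok, function(p)
      !any(gene_mask[max(1L, p - 1L):min(R, p + span)]) &&
        !any(mask[max(1L, p - 1L):min(R, p + span)]), logical(1))]
    if (!length(good)) next
    start <- sample(good, 1L)
    unit_ch <- seq_chars(unit)
    s[start:(start + span - 1L)] <- rep_len(unit_ch, span)
    # break accidental run extension at both ends
    pre <- start - 1L; post <- start + span
    if (pre >= 1L && s[pre] == unit_ch[length(unit_ch)])
      s[pre] <- sample(setdiff(DNA_BASES, s[pre]), 1L)
    if (post <= R && s[post] == unit_ch[1L])
      s[post] <- sample(setdiff(DNA_BASES, s[post]), 1L)
    mask[max(1L, start - 2L):min(R, post + 1L)] <- TRUE
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      start = start, end = start + span - 1L, unit = unit,
      unit_len = nchar(unit), copies = copies, stringsAsFactors = FALSE)
  }
  ssr <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else
    data.frame(start = integer(0), end = integer(0), unit = character(0),
               unit_len = integer(0), copies = integer(0))

  layout <- list(L = L, I = I, S = S, R = R, region = region, rate = rate,
                 mask = mask, features = feats, ycf1_ext = ycf1_ext,
                 diag = diag, diag_flank = diag_flank, ssr = ssr,
                 exp_bp = exp_bp, n_genes_placed = length(feats))

  full_seq <- chars_seq(c(s, revcomp_chars(s[(L + 1L):(L + I)])))
  anc_features <- .ancestor_full_features(layout)
  rec <- plastome_record("ANC0", "ancestor", full_seq, anc_features)
  attr(rec, "layout") <- layout
  rec
}

# Full-coordinate ancestor features: primary copies plus IR-mirrored
# duplicates and the rps19/ycf1 junction pseudofragments.
#' @keywords internal
.ancestor_full_features <- function(layout) {
  L <- layout$L; I <- layout$I; R <- layout$R
  glen <- R + I
  mirror <- function(a, b) c(glen + L + 1L - b, glen + L + 1L - a)
  flip <- function(x) if (x == "+") "-" else "+"
  out <- list()
  for (f in layout$features) {
    g <- f
    if (f$name == "ycf1") {
      g <- gene_feature("ycf1", f$kind, f$strand,
                        cbind(f$parts[1L, "start"], R + layout$ycf1_ext))
    }
    out[[length(out) + 1L]] <- g
    a <- min(g$parts[, "start"]); b <- max(g$parts[, "end"])
    if (a > L && b <= L + I) {  # wholly inside IRb: mirrored duplicate
      mparts <- g$parts
      for (i in seq_len(nrow(mparts))) {
        mv <- mirror(g$parts[i, "start"], g$parts[i, "end"])
        mparts[i, ] <- mv
      }
      mparts <- mparts[order(mparts[, "start"]), , drop = FALSE]
      out[[length(out) + 1L]] <- gene_feature(g$name, g$kind, flip(g$strand), mparts)
    }
  }
  # junction pseudofragments
  rps19 <- Filter(function(f) f$name == "rps19", layout$features)[[1L]]
  frag <- mirror(L + 1L, rps19$parts[1L, "end"])
  out[[length(out) + 1L]] <- gene_feature("rps19", "pseudogene", "+",
                                          cbind(frag[1L], frag[2L]))
  yfrag <- mirror(R + 1L, R + layout$ycf1_ext)
  out[[length(out) + 1L]] <- gene_feature("ycf1", "pseudogene", "-",
                                          cbind(yfrag[1L], yfrag[2L]))
  out
}

#' Evolve an ancestral plastome along the configured tree
#'
#' Substitutions are placed per branch with per-site probability
#' branch_length x region multiplier and resolved through the Ts:Tv kernel;
#' indel events (Poisson per branch, geometric lengths) are applied as
#' deletions (gaps) or insertions (new alignment columns inherited by all
#' descendants; inserted material does not evolve further). Planted
#' diagnostic columns are forced fixed-in-target / ancestral-in-background
#' and their flanks are mutation-masked; planted SSR loci undergo one-unit
#' slippage per accession; the optional IR expansion relabels the SSC tail of
#' one accession as IR and adds its reverse-complement copy at the IRb/SSC
#' junction. IRa mirrors IRb (and the captured tail) exactly in every
#' accession: concerted evolution by construction.
#'
#' Consumes the caller's RNG stream; use [simulate_plastome_family()] for the
#' seeded, deterministic entry point.
#'
#' @param ancestor result of [simulate_ancestor()] (carries the layout)
#' @param config the same [simulation_config()]
#' @return a `simulated_dataset` list: `records` (named list of
#'   [plastome_record()]s), `alignment` (a [plast_alignment()] of the true
#'   full-genome alignment), `config`, and `truth` (partitions, diagnostic
#'   columns, SNP columns per accession, indel events, SSR loci per
#'   accession, junction spans)
#' @export
evolve <- function(ancestor, config) {
  layout <- attr(ancestor, "layout")
  if (is.null(layout)) stop("ancestor lacks its simulation layout attribute")
  L <- layout$L; I <- layout$I; S <- layout$S; R <- layout$R
  tr <- ape::read.tree(text = config$tree)
  tips <- tr$tip.label
  stopifnot(all(tips %in% names(config$species)))
  kappa_p <- config$ts_tv / (config$ts_tv + 1)

  anc_chars <- seq_chars(substr(ancestor$sequence, 1L, R))
  mask <- layout$mask
  rate <- layout$rate
  n_tip <- length(tips)
  root <- n_tip + 1L

  ev_env <- new.env(parent = emptyenv())
  ev_env$events <- list()   # insertion events: id, pos, len, seq
  ev_env$leaf_rows <- list()
  ev_env$leaf_events <- list()
  ev_env$sub_log <- list()  # per-leaf substituted ancestor positions

  children_of <- function(node) tr$edge[tr$edge[, 1L] == node, 2L]
  edge_len <- function(node) tr$edge.length[which(tr$edge[, 2L] == node)]

  recurse <- function(node, chars, events, subbed) {
    kids <- children_of(node)
    if (!length(kids)) {
      acc <- tips[node]
      ev_env$leaf_rows[[acc]] <- chars
      ev_env$leaf_events[[acc]] <- events
      ev_env$sub_log[[acc]] <- subbed
      return(invisible(NULL))
    }
    for (kid in kids) {
      b <- edge_len(kid)
      ch <- chars; evs <- events; sub <- subbed
      if (b > 0) {
        p <- pmin(0.5, b * rate)
        idx <- which(stats::runif(R) < p & !mask & ch != "-")
        if (length(idx)) {
          ts <- stats::runif(length(idx)) < kappa_p
          cur <- ch[idx]
          new <- character(length(idx))
          new[ts] <- .TS_PARTNER[cur[ts]]
          if (any(!ts)) {
            pick <- stats::runif(sum(!ts)) < 0.5
            opts <- t(vapply(cur[!ts], function(bse) .TV_OPTIONS[[bse]], character(2)))
            new[!ts] <- ifelse(pick, opts[, 1L], opts[, 2L])
          }
          ch[idx] <- new
          sub <- c(sub, idx)
        }
        n_ind <- stats::rpois(1L, config$indel_rate * b * sum(rate))
        for (dummy in seq_len(n_ind)) {
          len <- min(50L, stats::rgeom(1L, 1 / config$indel_mean_len) + 1L)
          for (try in 1:20) {
            pos <- sample.int(R - len - 1L, 1L)
            if (any(mask[pos:(pos + len)])) next
            if (stats::runif(1L) < 0.5) {
              ch[pos:(pos + len - 1L)] <- "-"
            } else {
              id <- length(ev_env$events) + 1L
              ev_env$events[[id]] <- list(id = id, pos = pos, len = len,
                                          seq = .rand_dna(len, config$gc))
              evs <- c(evs, id)
            }
            break
          }
        }
      }
      recurse(kid, ch, evs, sub)
    }
  }
  recurse(root, anc_chars, integer(0), integer(0))

  # --- SSR slippage per accession ------------------------------------------
  ssr_truth <- list()
  for (acc in tips) {
    tab <- layout$ssr
    if (nrow(tab)) {
      tab$copies_realized <- tab$copies
      for (i in seq_len(nrow(tab))) {
        if (stats::runif(1L) >= config$ssr_slip_prob) next
        ulen <- tab$unit_len[i]
        thr <- .SSR_THRESHOLDS[[as.character(ulen)]]
        grow <- stats::runif(1L) < 0.5 || tab$copies[i] <= thr + 1L
        if (grow) {
          id <- length(ev_env$events) + 1L
          unit_ch <- seq_chars(tab$unit[i])
          ev_env$events[[id]] <- list(id = id, pos = tab$end[i], len = ulen,
                                      seq = unit_ch)
          ev_env$leaf_events[[acc]] <- c(ev_env$leaf_events[[acc]], id)
          tab$copies_realized[i] <- tab$copies[i] + 1L
        } else {
          span <- (tab$end[i] - ulen + 1L):tab$end[i]
          ev_env$leaf_rows[[acc]][span] <- "-"
          tab$copies_realized[i] <- tab$copies[i] - 1L
        }
      }
    }
    ssr_truth[[acc]] <- tab
  }

  # --- diagnostic allele enforcement ---------------------------------------
  target_accs <- names(config$species)[config$species == config$diagnostic$species]
  for (acc in tips) {
    forced <- if (acc %in% target_accs) layout$diag$target_allele else layout$diag$ancestral
    ev_env$leaf_rows[[acc]][layout$diag$pos] <- forced
  }
  # scrub accidental diagnostic columns: substitutions shared by the whole
  # target clade (stem-branch mutations) would satisfy the diagnostic
  # predicate; when the target has >= 2 accessions, revert one of them to the
  # reference allele so the planted set is exactly the diagnostic truth
  target_accs <- intersect(tips, target_accs)
  if (length(target_accs) >= 2L) {
    tmat <- do.call(rbind, ev_env$leaf_rows[target_accs])
    bmat <- do.call(rbind, ev_env$leaf_rows[setdiff(tips, target_accs)])
    ref_chars <- ev_env$leaf_rows[[config$reference_id]]
    fixed <- colSums(tmat == tmat[rep(1L, nrow(tmat)), , drop = FALSE]) == nrow(tmat)
    allele <- tmat[1L, ]
    no_gap <- allele != "-" & colSums(bmat == "-") == 0L
    bg_has <- colSums(t(t(bmat) == allele)) > 0L
    accidental <- which(fixed & no_gap & !bg_has)
    accidental <- setdiff(accidental, layout$diag$pos)
    if (length(accidental)) {
      repl <- ref_chars[accidental]
      usable <- repl != "-" & repl != allele[accidental]
      ev_env$leaf_rows[[target_accs[2L]]][accidental[usable]] <- repl[usable]
    }
  }

  # --- build the global reduced alignment ----------------------------------
  events <- ev_env$events
  ev_ord <- if (length(events)) {
    order(vapply(events, `[[`, 0L, "pos"), vapply(events, `[[`, 0L, "id"))
  } else integer(0)
  ins_len <- vapply(events, `[[`, 0L, "len")
  ncol_red <- R + sum(ins_len)
  base_col <- integer(R)
  ev_cols <- vector("list", length(events))
  anchor <- integer(ncol_red)
  col <- 0L
  ei <- 1L
  for (p in seq_len(R)) {
    col <- col + 1L
    base_col[p] <- col
    anchor[col] <- p
    while (ei <= length(ev_ord) && events[[ev_ord[ei]]]$pos == p) {
      e <- events[[ev_ord[ei]]]
      ev_cols[[e$id]] <- seq.int(col + 1L, col + e$len)
      anchor[(col + 1L):(col + e$len)] <- p
      col <- col + e$len
      ei <- ei + 1L
    }
  }

  m <- matrix("-", nrow = n_tip, ncol = ncol_red, dimnames = list(tips, NULL))
  for (acc in tips) {
    row <- rep("-", ncol_red)
    row[base_col] <- ev_env$leaf_rows[[acc]]
    for (id in ev_env$leaf_events[[acc]]) row[ev_cols[[id]]] <- events[[id]]$seq
    m[acc, ] <- row
  }

  # --- splice in expansion block and IRa mirror ----------------------------
  exp_acc <- if (!is.null(config$ir_expansion)) config$ir_expansion$accession else NULL
  e0 <- layout$exp_bp
  cols_lsc <- which(anchor <= L)
  cols_irb <- which(anchor > L & anchor <= L + I)
  cols_ssc <- which(anchor > L + I)
  cols_tail <- if (!is.null(exp_acc)) which(anchor > R - e0) else integer(0)
  cols_pre <- c(cols_lsc, cols_irb)

  comp_block <- function(block) {
    out <- matrix(complement_chars(as.vector(block)), nrow = nrow(block))
    rownames(out) <- rownames(block)
    out
  }
  mirror_block <- comp_block(m[, rev(cols_irb), drop = FALSE])
  if (!is.null(exp_acc)) {
    exp_block <- matrix("-", nrow = n_tip, ncol = length(cols_tail),
                        dimnames = list(tips, NULL))
    exp_block[exp_acc, ] <- complement_chars(m[exp_acc, rev(cols_tail)])
    full <- cbind(m[, cols_pre, drop = FALSE], exp_block,
                  m[, cols_ssc, drop = FALSE], mirror_block)
  } else {
    full <- cbind(m[, cols_pre, drop = FALSE],
                  m[, cols_ssc, drop = FALSE], mirror_block)
  }
  colnames(full) <- NULL
  n_exp_cols <- if (!is.null(exp_acc)) length(cols_tail) else 0L

  aln <- plast_alignment(full, config$species[tips], config$reference_id)

  # full-alignment column of an ancestor position
  full_col_of <- function(p) {
    rc <- base_col[p]
    if (anchor[rc] > L + I) rc + n_exp_cols else rc
  }

  # --- per-accession records, partitions, features -------------------------
  records <- list()
  partitions <- list()
  junction_rows <- list()
  for (acc in tips) {
    row_full <- full[acc, ]
    leafpos <- cumsum(row_full != "-")
    glen <- leafpos[length(leafpos)]
    lsc_b <- sum(m[acc, cols_lsc] != "-")
    irb_b <- sum(m[acc, cols_irb] != "-")
    ssc_b <- sum(m[acc, cols_ssc] != "-")
    tail_b <- if (length(cols_tail)) sum(m[acc, cols_tail] != "-") else 0L
    expanded <- !is.null(exp_acc) && acc == exp_acc
    l1 <- lsc_b
    l2 <- if (expanded) irb_b + tail_b else irb_b
    l3 <- if (expanded) ssc_b - tail_b else ssc_b
    partitions[[acc]] <- data.frame(
      accession = acc, region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(1L, l1 + 1L, l1 + l2 + 1L, l1 + l2 + l3 + 1L),
      end = c(l1, l1 + l2, l1 + l2 + l3, glen),
      stringsAsFactors = FALSE)

    map_iv <- function(fa, fb) {
      ca <- full_col_of(fa); cb <- full_col_of(fb)
      la <- if (row_full[ca] != "-") leafpos[ca] else leafpos[ca] + 1L
      lb <- leafpos[cb]
      if (lb < la) NULL else c(la, lb)
    }
    feats <- list()
    for (f in layout$features) {
      parts <- NULL
      for (i in seq_len(nrow(f$parts))) {
        iv <- map_iv(f$parts[i, "start"], f$parts[i, "end"])
        if (!is.null(iv)) parts <- rbind(parts, iv)
      }
      if (is.null(parts)) next
      if (f$name == "ycf1") parts[nrow(parts), 2L] <- parts[nrow(parts), 2L] + layout$ycf1_ext
      feats[[length(feats) + 1L]] <- gene_feature(f$name, f$kind, f$strand, parts)
    }
    # IR-internal duplicates mirrored into the other copy; the mirror of
    # position p under IRa = revcomp(IRb) with IRa terminal is glen + l1 + 1 - p
    mirror <- function(a, b) c(glen + l1 + 1L - b, glen + l1 + 1L - a)
    flip <- function(x) if (x == "+") "-" else "+"
    irb_iv <- c(l1 + 1L, l1 + l2)
    ira_iv <- c(l1 + l2 + l3 + 1L, glen)
    primary <- feats
    for (f in primary) {
      a <- min(f$parts[, "start"]); b <- max(f$parts[, "end"])
      if ((a >= irb_iv[1L] && b <= irb_iv[2L]) ||
          (a >= ira_iv[1L] && b <= ira_iv[2L])) {
        mp <- t(apply(f$parts, 1L, function(p) mirror(p[1L], p[2L])))
        mp <- mp[order(mp[, 1L]), , drop = FALSE]
        feats[[length(feats) + 1L]] <- gene_feature(f$name, f$kind, flip(f$strand), mp)
      }
    }
    # junction pseudofragments: rps19 portion inside IRb, ycf1 portion inside IRa
    rps19_f <- Filter(function(f) f$name == "rps19", primary)
    if (length(rps19_f)) {
      b <- max(rps19_f[[1L]]$parts[, "end"])
      if (b > l1 && min(rps19_f[[1L]]$parts[, "start"]) <= l1) {
        fr <- mirror(l1 + 1L, b)
        feats[[length(feats) + 1L]] <- gene_feature("rps19", "pseudogene", "+",
                                                    cbind(fr[1L], fr[2L]))
        junction_rows[[length(junction_rows) + 1L]] <- data.frame(
          accession = acc, junction = "JLB", gene = "rps19",
          side_before = l1 - min(rps19_f[[1L]]$parts[, "start"]) + 1L,
          side_after = b - l1, stringsAsFactors = FALSE)
      }
    }
    ycf1_f <- Filter(function(f) f$name == "ycf1", primary)
    if (length(ycf1_f)) {
      a <- min(ycf1_f[[1L]]$parts[, "start"]); b <- max(ycf1_f[[1L]]$parts[, "end"])
      jsa <- l1 + l2 + l3
      if (a <= jsa && b > jsa) {
        fr <- mirror(jsa + 1L, b)
        feats[[length(feats) + 1L]] <- gene_feature("ycf1", "pseudogene", "-",
                                                    cbind(fr[1L], fr[2L]))
        junction_rows[[length(junction_rows) + 1L]] <- data.frame(
          accession = acc, junction = "JSA", gene = "ycf1",
          side_before = jsa - a + 1L, side_after = b - jsa,
          stringsAsFactors = FALSE)
      }
    }
    seq_str <- chars_seq(row_full[row_full != "-"])
    records[[acc]] <- plastome_record(acc, unname(config$species[acc]), seq_str, feats)
  }

  # --- truth tables --------------------------------------------------------
  diag_cols <- vapply(layout$diag$pos, full_col_of, 0L)
  diag_truth <- data.frame(column = diag_cols,
                           pos = layout$diag$pos,
                           target_allele = layout$diag$target_allele,
                           background_allele = layout$diag$ancestral,
                           stringsAsFactors = FALSE)

  ref_row <- full[config$reference_id, ]
  snp_cols <- lapply(tips, function(acc) {
    if (acc == config$reference_id) return(integer(0))
    q <- full[acc, ]
    cols <- integer(0)
    for (jj in seq_along(q)) {  # deliberate plain scan: generation-side truth
      if (ref_row[jj] != "-" && q[jj] != "-" && ref_row[jj] != q[jj]) {
        cols <- c(cols, jj)
      }
    }
    cols
  })
  names(snp_cols) <- tips

  structure(list(
    records = records,
    alignment = aln,
    config = config,
    truth = list(partitions = do.call(rbind, partitions),
                 diagnostic = diag_truth,
                 snp_columns = snp_cols,
                 ssr = ssr_truth,
                 junctions = if (length(junction_rows)) do.call(rbind, junction_rows) else NULL,
                 substituted = ev_env$sub_log,
                 exp_bp = layout$exp_bp)
  ), class = "simulated_dataset")
}

#' Simulate a plastome family with known truth
#'
#' Seeded, deterministic wrapper: `set.seed(config$seed)`, then
#' [simulate_ancestor()] and [evolve()]. Identical configs (including seed)
#' produce byte-identical datasets.
#'
#' @param config a [simulation_config()]
#' @return a `simulated_dataset` (see [evolve()])
#' @export
simulate_plastome_family <- function(config = simulation_config()) {
  set.seed(config$seed)
  anc <- simulate_ancestor(config)
  ds <- evolve(anc, config)
  ds$ancestor <- anc
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d accessions, alignment %s columns, %d diagnostic columns\n",
              length(x$records), format(n_columns(x$alignment), big.mark = ","),
              nrow(x$truth$diagnostic)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one GenBank flat file and one FASTA per accession, the true aligned
#' FASTA, the accession-to-species TSV and the truth tables (via
#' [truth_report()]).
#'
#' @param dataset a `simulated_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(dataset$records)) {
    rec <- dataset$records[[acc]]
    write_genbank(rec, file.path(dir, paste0(acc, ".gb")))
    set <- Biostrings::DNAStringSet(rec$sequence)
    names(set) <- acc
    Biostrings::writeXStringSet(set, file.path(dir, paste0(acc, ".fasta")))
  }
  write_alignment(dataset$alignment, file.path(dir, "alignment.fasta"),
                  file.path(dir, "species_map.tsv"))
  truth_report(dataset, file.path(dir, "truth"))
  invisible(dir)
}

#' Write the truth tables of a simulated dataset as TSVs
#'
#' @param dataset a `simulated_dataset`
#' @param dir output directory for the TSV bundle
#' @return named vector of written paths, invisibly
#' @export
truth_report <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dataset$truth
  paths <- c()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  w(tr$partitions, "partitions.tsv")
  w(tr$diagnostic, "diagnostic_columns.tsv")
  snp <- do.call(rbind, lapply(names(tr$snp_columns), function(acc) {
    cols <- tr$snp_columns[[acc]]
    if (!length(cols)) return(NULL)
    data.frame(accession = acc, column = cols, stringsAsFactors = FALSE)
  }))
  w(snp %||% data.frame(accession = character(0), column = integer(0)),
    "snp_columns.tsv")
  ssr <- do.call(rbind, lapply(names(tr$ssr), function(acc) {
    tab <- tr$ssr[[acc]]
    if (!nrow(tab)) return(NULL)
    cbind(accession = acc, tab)
  }))
  w(ssr %||% data.frame(), "ssr_loci.tsv")
  if (!is.null(tr$junctions)) w(tr$junctions, "junction_spans.tsv")
  invisible(paths)
}

#' Simulate a codon-aligned CDS pair under a fixed dN/dS ratio
#'
#' A stop-free random CDS is copied and the copy mutated: at every codon
#' position each possible base change is applied with probability `t` when
#' synonymous and `t * omega` when nonsynonymous (changes creating stop
#' codons are skipped). Used to check that the counting-method Ka/Ks
#' estimator recovers a planted omega.
#'
#' @param n_codons number of codons
#' @param t per-change synonymous mutation probability
#' @param omega nonsynonymous:synonymous rate ratio
#' @return list with `cds1`, `cds2` (equal-length strings)
#' @export
simulate_cds_pair <- function(n_codons, t = 0.02, omega = 1) {
  code <- .genetic_code()
  non_stop <- names(code)[code != "*"]
  cod <- sample(non_stop, n_codons, replace = TRUE)
  cod2 <- cod
  for (i in seq_len(n_codons)) {
    cur <- cod2[i]
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cur, pos, pos))) {
        alt <- cur
        substr(alt, pos, pos) <- b
        if (code[[alt]] == "*") next
        p <- if (code[[alt]] == code[[cur]]) t else t * omega
        if (stats::runif(1L) < p) {
          cur <- alt
          break  # at most one change per position
        }
      }
    }
    cod2[i] <- cur
  }
  list(cds1 = paste(cod, collapse = ""), cds2 = paste(cod2, collapse = ""))
}
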