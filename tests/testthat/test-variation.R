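# SNP/indel calling, Ts/Tv classing, nucleotide diversity and p-distances,
# each checked against an independent brute-force oracle.

test_that("substitution classing matches enumeration over all 12 ordered pairs", {
  bases <- c("A", "C", "G", "T")
  purine <- function(b) b %in% c("A", "G")
  n_ts <- 0L; n_tv <- 0L
  for (r in bases) for (a in setdiff(bases, r)) {
    expected <- if (purine(r) == purine(a)) "Ts" else "Tv"  # independent rule
    expect_equal(classify_substitution(r, a), expected)
    if (expected == "Ts") n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
  }
  expect_equal(n_ts, 4L)
  expect_equal(n_tv, 8L)
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("call_snps matches simple examples and a Hamming oracle", {
  aln <- make_alignment(list(ref = "ACGT", q = "ACGA"), reference_id = "ref")
  out <- call_snps(aln, "q")
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref_pos, 4L)
  expect_equal(out$ref_allele, "T")
  expect_equal(out$alt_allele, "A")
  expect_equal(out$ts_tv, "Tv")

  gap <- make_alignment(list(ref = "AC-T", q = "ACGT"), reference_id = "ref")
  expect_equal(nrow(call_snps(gap, "q")), 0L)

  expect_equal(nrow(call_snps(aln, "ref")), 0L)

  # fuzzed gap-free pairs: SNP count equals Hamming distance
  set.seed(31)
  for (rep in 1:10) {
    a <- rand_seq(300); b <- rand_seq(300)
    al <- make_alignment(list(ref = a, q = b), reference_id = "ref")
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(nrow(call_snps(al, "q")), hamming)
  }
})

test_that("Ts + Tv counts equal the SNP total for every query", {
  ds <- small_dataset()
  for (q in setdiff(rownames(ds$alignment$matrix), ds$alignment$reference_id)) {
    snps <- call_snps(ds$alignment, q)
    expect_equal(sum(snps$ts_tv == "Ts") + sum(snps$ts_tv == "Tv"), nrow(snps))
  }
})

test_that("SNP region attribution sums to the overall total", {
  ds <- small_dataset()
  ref <- ds$records[[ds$alignment$reference_id]]
  part <- detect_partition(ref$sequence)
  ann <- suppressWarnings(annotate_regions(ref))
  snps <- call_snps(ds$alignment, "PMAR1", part, ann)
  expect_false(anyNA(snps$structural_region))
  expect_equal(sum(table(snps$structural_region)), nrow(snps))
  expect_equal(sum(table(snps$functional_region)), nrow(snps))
})

test_that("call_indels emits one event per maximal one-sided gap run", {
  aln <- make_alignment(list(ref = "ACGTACGT", q = "ACG--CGT"), reference_id = "ref")
  out <- call_indels(aln, "q")
  expect_equal(nrow(out), 1L)
  expect_equal(out$kind, "deletion")
  expect_equal(out$length, 2L)

  ins <- make_alignment(list(ref = "A---T", q = "ACGGT"), reference_id = "ref")
  out2 <- call_indels(ins, "q")
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$kind, "insertion")
  expect_equal(out2$length, 3L)

  # double-gapped columns are ignored entirely
  both <- make_alignment(list(ref = "AC--GT", q = "AC--GT"), reference_id = "ref")
  expect_equal(nrow(call_indels(both, "q")), 0L)

  # fuzzed: total gap bases equal the sum of event lengths
  set.seed(77)
  for (rep in 1:10) {
    n <- 200
    r <- strsplit(rand_seq(n), "")[[1]]
    q <- strsplit(rand_seq(n), "")[[1]]
    r[sample(n, 20)] <- "-"
    q[sample(n, 20)] <- "-"
    al <- make_alignment(list(ref = paste(r, collapse = ""),
                              q = paste(q, collapse = "")), reference_id = "ref")
    out3 <- call_indels(al, "q")
    one_sided <- sum(xor(r == "-", q == "-"))
    expect_equal(sum(out3$length), one_sided)
  }
})

test_that("window pi reproduces the hand-computed 3-row example", {
  # rows ACGT/ACGA/ACGT: pair diffs (1,0,1)/4 usable -> mean = 0.1667
  aln <- make_alignment(list(a = "ACGT", b = "ACGA", c = "ACGT"))
  wp <- window_pi(aln, window = 4)
  expect_equal(wp$pi, ((1 / 4) + 0 + (1 / 4)) / 3, tolerance = 1e-12)
  expect_equal(wp$usable_sites, 4L)

  ident <- make_alignment(list(a = "ACGTACGT", b = "ACGTACGT"))
  wpi <- window_pi(ident, window = 4)
  expect_true(all(wpi$pi == 0))
})

test_that("pi equals explicit pair enumeration for n <= 6 rows", {
  set.seed(13)
  for (rep in 1:8) {
    nrows <- sample(2:6, 1)
    len <- 120
    rows <- lapply(seq_len(nrows), function(i) {
      ch <- strsplit(rand_seq(len), "")[[1]]
      ch[sample(len, 8)] <- "-"
      paste(ch, collapse = "")
    })
    names(rows) <- paste0("r", seq_len(nrows))
    aln <- make_alignment(rows)
    # oracle: direct double loop over pairs and sites
    mats <- do.call(rbind, strsplit(unlist(rows), ""))
    vals <- c()
    for (i in seq_len(nrows - 1)) for (j in seq.int(i + 1, nrows)) {
      u <- 0L; d <- 0L
      for (col in seq_len(len)) {
        x <- mats[i, col]; y <- mats[j, col]
        if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
          u <- u + 1L
          if (x != y) d <- d + 1L
        }
      }
      if (u > 0) vals <- c(vals, d / u)
    }
    expect_equal(window_pi(aln, window = len)$pi, mean(vals), tolerance = 1e-12)
    expect_equal(column_pi(aln, seq_len(len)), mean(vals), tolerance = 1e-12)
  }
})

test_that("locus pi recovers planted rate ordering and class means", {
  # two loci with very different divergence
  set.seed(99)
  lowA <- rand_seq(300)
  hi_base <- strsplit(rand_seq(300), "")[[1]]
  hi_mut <- hi_base
  hi_mut[sample(300, 45)] <- sapply(hi_base[sample(300, 45)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1))
  rows <- list(ref = paste0(lowA, paste(hi_base, collapse = "")),
               q = paste0(lowA, paste(hi_mut, collapse = "")))
  aln <- make_alignment(rows, reference_id = "ref")
  rec <- plastome_record("ref", "sp", rows$ref, list(
    gene_feature("quiet", "CDS", "+", cbind(1L, 300L)),
    gene_feature("hot", "CDS", "+", cbind(301L, 600L))
  ))
  ann <- annotate_regions(rec)
  lp <- locus_pi(aln, ann)
  expect_gt(lp$pi[lp$locus == "hot"], lp$pi[lp$locus == "quiet"])
  # class mean is the unweighted mean of member loci
  cm <- attr(lp, "class_means")
  cds <- lp[lp$class == "CDS", ]
  expect_equal(unname(cm[["CDS"]]), mean(cds$pi), tolerance = 1e-12)
})

test_that("hotspot ranking is order-invariant and k-capped", {
  ds <- small_dataset()
  ref <- ds$records[[ds$alignment$reference_id]]
  ann <- suppressWarnings(annotate_regions(ref))
  lp <- locus_pi(ds$alignment, ann)
  hs <- rank_hotspots(lp, k = 10)
  expect_lte(nrow(hs), 10L)
  expect_true(!is.unsorted(rev(hs$pi)))
  # permuting the input leaves the ranking identical
  perm <- lp[sample(nrow(lp)), ]
  expect_equal(rank_hotspots(perm, k = 10), hs)
  # k larger than the table returns the whole (defined-pi) table
  all_hs <- rank_hotspots(lp, k = 10 * nrow(lp))
  expect_equal(nrow(all_hs), sum(!is.na(lp$pi)))
})

test_that("p-distance matrix is symmetric with zero diagonal and exact values", {
  one_diff <- make_alignment(list(
    a = paste0(strrep("A", 99), "G"),
    b = strrep("A", 100)
  ))
  pd <- pairwise_p_distance(one_diff)
  expect_equal(pd["a", "b"], 0.01)
  expect_equal(pd["a", "a"], 0)
  ds <- small_dataset()
  m <- pairwise_p_distance(ds$alignment)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("intraspecific diversity averages over conspecific accession pairs", {
  ds <- small_dataset()
  intra <- intraspecific_diversity(ds$alignment)
  expect_equal(intra$species, "Plantago lanceolata")
  pd <- pairwise_p_distance(ds$alignment)
  expect_equal(intra$mean_p, pd["PLAN1", "PLAN2"])
  # conspecific accessions are far closer than heterospecific ones
  expect_lt(intra$mean_p, pd["PLAN1", "POVA1"] / 3)
})
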