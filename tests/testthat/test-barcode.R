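# Diagnostic SNP discovery, allele-specific primer design and in-silico PCR.

test_that("a fixed target column absent from the background is diagnostic", {
  rows <- list(
    t1 = "AAATAAAAAA", t2 = "AAATAAAAAA", t3 = "AAATAAAAAA",
    b1 = "AAACAAAAAA", b2 = "AAACAAAAAA", b3 = "AAACAAAAAA", b4 = "AAACAAAAAA")
  sp <- c(t1 = "target", t2 = "target", t3 = "target",
          b1 = "bg1", b2 = "bg2", b3 = "bg3", b4 = "bg4")
  aln <- make_alignment(rows, species = sp, reference_id = "b1")
  snps <- find_diagnostic_snps(aln, "target", flank = 3)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$column, 4L)
  expect_equal(snps$target_allele, "T")
  expect_equal(snps$flank_conservation, 1)
})

test_that("columns polymorphic within the target species are excluded", {
  rows <- list(t1 = "AAATAA", t2 = "AAACAA", b1 = "AAAGAA")
  sp <- c(t1 = "target", t2 = "target", b1 = "bg")
  aln <- make_alignment(rows, species = sp, reference_id = "b1")
  expect_equal(nrow(find_diagnostic_snps(aln, "target", flank = 2)), 0L)
})

test_that("gapped or N columns are never diagnostic", {
  rows <- list(t1 = "AATAA", t2 = "AATAA", b1 = "AA-AA", b2 = "AANAA")
  sp <- c(t1 = "target", t2 = "target", b1 = "b", b2 = "c")
  aln <- make_alignment(rows, species = sp, reference_id = "b1")
  expect_equal(nrow(find_diagnostic_snps(aln, "target", flank = 2)), 0L)
})

test_that("missing target species raises an error", {
  aln <- make_alignment(list(a = "ACGT", b = "ACGT"))
  expect_error(find_diagnostic_snps(aln, "nonexistent"), "absent")
})

test_that("planted diagnostic columns are recovered exactly with no spurious calls", {
  ds <- small_dataset()
  snps <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata")
  expect_setequal(snps$column, ds$truth$diagnostic$column)
  # alleles match the plan
  merged <- merge(snps, ds$truth$diagnostic, by = "column")
  expect_equal(merged$target_allele.x, merged$target_allele.y)
})

test_that("reported diagnostic columns always satisfy the predicate (brute force)", {
  ds <- small_dataset()
  snps <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata",
                               min_flank_conservation = 0)
  m <- ds$alignment$matrix
  tgt <- accessions_of(ds$alignment, "Plantago lanceolata")
  bg <- setdiff(rownames(m), tgt)
  for (i in seq_len(nrow(snps))) {
    col <- snps$column[i]
    expect_true(all(m[tgt, col] == snps$target_allele[i]))
    expect_false(any(m[bg, col] == snps$target_allele[i]))
    expect_true(all(m[, col] %in% c("A", "C", "G", "T")))
  }
})

test_that("adding a background accession can only shrink the diagnostic set", {
  ds <- small_dataset()
  full <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata",
                               min_flank_conservation = 0)
  reduced_mat <- ds$alignment$matrix[setdiff(rownames(ds$alignment$matrix), "PMAR1"), ]
  aln2 <- plast_alignment(reduced_mat, ds$alignment$species, "POVA1")
  fewer_bg <- find_diagnostic_snps(aln2, "Plantago lanceolata",
                                   min_flank_conservation = 0)
  expect_true(all(full$column %in% fewer_bg$column))
})

test_that("designed primers end 3' on the diagnostic allele and fit constraints", {
  ds <- small_dataset()
  snps <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata")
  pairs <- design_diagnostic_pair(ds$alignment, snps)
  expect_gt(nrow(pairs), 0L)
  cons <- primer_constraints()
  for (i in seq_len(nrow(pairs))) {
    fwd <- pairs$forward[i]; rev_ <- pairs$reverse[i]
    expect_true(nchar(fwd) %in% cons$primer_len)
    expect_true(nchar(rev_) %in% cons$primer_len)
    # 3'-terminal base equals the target allele at the anchor columns
    tcol_f <- snps$target_allele[match(TRUE, !is.na(match(snps$column, snps$column)))]
    anchors <- snps$target_allele[order(snps$column)]
    expect_true(substr(fwd, nchar(fwd), nchar(fwd)) %in% anchors)
    expect_true(substr(rev_, nchar(rev_), nchar(rev_)) %in%
                  chartr("ACGT", "TGCA", anchors))
    expect_gte(pairs$product_size[i], cons$product[1])
    expect_lte(pairs$product_size[i], cons$product[2])
    expect_gte(pairs$tm_fwd[i], cons$tm[1]); expect_lte(pairs$tm_fwd[i], cons$tm[2])
    expect_gte(pairs$gc_fwd[i], cons$gc[1]); expect_lte(pairs$gc_fwd[i], cons$gc[2])
  }
})

test_that("SNP pairs too close for the product range give an empty result", {
  ds <- small_dataset()
  snps <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata")
  tight <- primer_constraints(product = c(100000L, 200000L))
  out <- design_diagnostic_pair(ds$alignment, snps, tight)
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "message"), "single-anchor")
})

test_that("the control pair sits in invariant sequence near the requested size", {
  ds <- small_dataset()
  ctrl <- design_control_pair(ds$alignment, target_product = 400L)
  expect_equal(ctrl$role, "control")
  expect_lt(abs(ctrl$product_size - 400L), 150L)
  inv <- plastomarker:::.invariant_columns(ds$alignment)
  # both primers drawn from invariant columns: they bind every accession
  for (acc in names(ds$records)) {
    amp <- in_silico_pcr(ds$records[[acc]], ctrl)
    expect_equal(nrow(amp), 1L, info = acc)
    expect_equal(amp$fwd_mismatches + amp$rev_mismatches, 0L, info = acc)
  }
})

test_that("diagnostic pairs amplify all targets and no background accession", {
  ds <- small_dataset()
  snps <- find_diagnostic_snps(ds$alignment, "Plantago lanceolata")
  pairs <- design_diagnostic_pair(ds$alignment, snps)
  pr <- pairs[1, ]
  targets <- accessions_of(ds$alignment, "Plantago lanceolata")
  for (acc in names(ds$records)) {
    amp <- in_silico_pcr(ds$records[[acc]], pr)
    if (acc %in% targets) {
      expect_equal(nrow(amp), 1L, info = acc)
    } else {
      expect_equal(nrow(amp), 0L, info = acc)
    }
  }
  # the target product has the designed size on the design template
  amp1 <- in_silico_pcr(ds$records[[targets[1]]], pr)
  expect_equal(amp1$size, pr$product_size)
})

test_that("3'-strict binding rejects a terminal mismatch but allows internal ones", {
  set.seed(50)
  template <- rand_seq(600)
  primer <- substr(template, 101, 122)
  rev_primer <- revcomp(substr(template, 401, 422))
  pair <- list(forward = primer, reverse = rev_primer)
  expect_equal(nrow(in_silico_pcr(template, pair, circular = FALSE)), 1L)
  # flip the 3'-terminal base of the forward primer: no amplification
  bad <- primer
  substr(bad, 22, 22) <- setdiff(c("A", "C", "G", "T"), substr(primer, 22, 22))[1]
  expect_equal(nrow(in_silico_pcr(template, list(forward = bad, reverse = rev_primer),
                                  circular = FALSE)), 0L)
  # two internal mismatches still bind
  int2 <- primer
  substr(int2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(primer, 5, 5))[1]
  substr(int2, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(primer, 9, 9))[1]
  expect_equal(nrow(in_silico_pcr(template, list(forward = int2, reverse = rev_primer),
                                  circular = FALSE)), 1L)
})

test_that("nearest-neighbor Tm behaves physically", {
  expect_lt(primer_tm(strrep("A", 20)), primer_tm(strrep("G", 20)))
  set.seed(60)
  for (rep in 1:5) {
    p <- rand_seq(22, gc = 0.5)
    expect_equal(primer_tm(p), primer_tm(revcomp(p)), tolerance = 1e-9)
  }
  # a 20-mer at 50% GC melts in a plausible PCR range
  tm <- primer_tm("ACGTACGTGCATGCATACGC")
  expect_gt(tm, 45); expect_lt(tm, 70)
})
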