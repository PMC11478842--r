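# GenBank parsing, coordinate conventions, region annotation and variant
# table round trips.

test_that("GenBank coordinates map to 1-based closed internal intervals", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST1 2000 bp    DNA     circular PLN 01-JAN-2024",
    "ACCESSION   TEST1",
    "  ORGANISM  Plantago testii",
    "FEATURES             Location/Qualifiers",
    "     source          1..2000",
    "     CDS             101..1528",
    "                     /gene=\"rbcL\"",
    "     CDS             join(10..20,50..70)",
    "                     /gene=\"twoexon\"",
    "     tRNA            complement(1600..1672)",
    "                     /gene=\"trnH-GUG\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"
  ), gb)
  # pad ORIGIN to full length by rewriting with a real sequence
  rec0 <- plastome_record("TEST1", "Plantago testii", rand_seq(2000))
  rec0$features <- list(
    gene_feature("rbcL", "CDS", "+", cbind(101L, 1528L)),
    gene_feature("twoexon", "CDS", "+", rbind(c(10L, 20L), c(50L, 70L))),
    gene_feature("trnH-GUG", "tRNA", "-", cbind(1600L, 1672L))
  )
  write_genbank(rec0, gb)
  rec <- read_genbank(gb)

  expect_equal(rec$accession, "TEST1")
  expect_equal(rec$species, "Plantago testii")
  expect_equal(rec$length, 2000L)
  rbcl <- rec$features[[which(vapply(rec$features, `[[`, "", "name") == "rbcL")]]
  expect_equal(unname(rbcl$parts[1, ]), c(101L, 1528L))
  two <- rec$features[[which(vapply(rec$features, `[[`, "", "name") == "twoexon")]]
  expect_equal(unname(two$parts[, "start"]), c(10L, 50L))
  expect_equal(unname(two$parts[, "end"]), c(20L, 70L))
  expect_equal(two$intron_count, 1L)
  trn <- rec$features[[which(vapply(rec$features, `[[`, "", "name") == "trnH-GUG")]]
  expect_equal(trn$strand, "-")
})

test_that("GenBank round trip is coordinate-bijective on fuzzed records", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3000:6000, 1)
    feats <- list()
    pos <- 50L
    while (pos + 400L < n - 100L) {
      len <- sample(90:300, 1)
      kind <- sample(c("CDS", "tRNA", "rRNA"), 1)
      if (runif(1) < 0.3) {
        e1 <- len %/% 3
        feats[[length(feats) + 1L]] <- gene_feature(
          paste0("g", length(feats)), kind, sample(c("+", "-"), 1),
          rbind(c(pos, pos + e1), c(pos + e1 + 40L, pos + len)))
      } else {
        feats[[length(feats) + 1L]] <- gene_feature(
          paste0("g", length(feats)), kind, sample(c("+", "-"), 1),
          cbind(pos, pos + len))
      }
      pos <- pos + len + sample(60:200, 1)
    }
    rec <- plastome_record(paste0("FZ", rep), "fuzz", rand_seq(n), feats)
    gb <- tempfile(fileext = ".gb")
    write_genbank(rec, gb)
    back <- read_genbank(gb)
    expect_equal(back$sequence, rec$sequence)
    expect_equal(length(back$features), length(feats))
    for (i in seq_along(feats)) {
      expect_equal(back$features[[i]]$parts, feats[[i]]$parts)
      expect_equal(back$features[[i]]$strand, feats[[i]]$strand)
      expect_equal(back$features[[i]]$intron_count, feats[[i]]$intron_count)
    }
  }
})

test_that("records with no features annotate as all-IGS", {
  rec <- plastome_record("EMPTY", "none", rand_seq(100))
  ann <- annotate_regions(rec)
  expect_true(all(ann$class == "IGS"))
  expect_equal(unname(region_class_counts(ann)[["IGS"]]), 100L)
})

test_that("region classes partition the genome and introns are classed", {
  # single two-part CDS: inter-part gap is intron
  rec <- plastome_record("P1", "toy", rand_seq(100), list(
    gene_feature("gA", "CDS", "+", rbind(c(11L, 30L), c(51L, 70L)))
  ))
  ann <- annotate_regions(rec)
  expect_equal(unique(ann$class[31:50]), "intron")
  expect_equal(unique(ann$class[11:30]), "CDS")
  expect_equal(unique(ann$class[1:10]), "IGS")
  expect_equal(sum(region_class_counts(ann)), rec$length)

  # fuzzed: classes always partition the genome
  set.seed(7)
  for (rep in 1:5) {
    ds_rec <- plastome_record("F", "f", rand_seq(500), list(
      gene_feature("a", "CDS", "+", cbind(40L, 120L)),
      gene_feature("b", "tRNA", "-", cbind(200L, 270L))
    ))
    ann2 <- annotate_regions(ds_rec)
    expect_equal(sum(region_class_counts(ann2)), 500L)
  }
})

test_that("spacer names use flanking gene order on the forward strand", {
  rec <- plastome_record("SP", "toy", rand_seq(300), list(
    gene_feature("infA", "CDS", "+", cbind(10L, 60L)),
    gene_feature("rps8", "CDS", "-", cbind(150L, 200L))
  ))
  ann <- annotate_regions(rec)
  expect_equal(unique(ann$locus[61:149]), "infA-rps8")
})

test_that("per-class base totals equal planted totals on a synthetic genome", {
  ds <- small_dataset()
  rec <- ds$records[["POVA1"]]
  ann <- suppressWarnings(annotate_regions(rec))
  counts <- region_class_counts(ann)
  expect_equal(sum(counts), rec$length)
  # every CDS/tRNA/rRNA exon base must be classed CDS
  exonic <- unique(unlist(lapply(rec$features, function(f)
    if (f$kind == "pseudogene") NULL else
      unlist(apply(f$parts, 1, function(p) seq.int(p[1], p[2]), simplify = FALSE)))))
  expect_true(all(ann$class[exonic] == "CDS"))
})

test_that("alignment read/write round-trips bit-identically with column map", {
  aln <- make_alignment(list(r1 = "AC-T", r2 = "ACGT"), reference_id = "r2")
  expect_equal(aln$column_map, c(1L, 2L, 3L, 4L))
  aln2 <- make_alignment(list(r1 = "A-CT", r2 = "AACT"), reference_id = "r1")
  expect_true(is.na(aln2$column_map[2]))
  expect_equal(aln2$column_map[c(1, 3, 4)], c(1L, 2L, 3L))

  ds <- small_dataset()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_alignment(ds$alignment, fa, tsv)
  back <- read_alignment(fa, tsv, ds$alignment$reference_id)
  expect_identical(back$matrix, ds$alignment$matrix)
  expect_identical(back$column_map, ds$alignment$column_map)
  expect_identical(unname(back$species), unname(ds$alignment$species))
})

test_that("read_alignment rejects ragged rows and unmapped accessions", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tspecies", "a\tx", "b\ty"), tsv)
  expect_error(read_alignment(fa, tsv, "a"), "ragged")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  writeLines(c("accession\tspecies", "a\tx"), tsv)
  expect_error(read_alignment(fa, tsv, "a"), "species map")
})

test_that("variant tables round-trip through minimal VCF and pass lint", {
  ds <- small_dataset()
  rec <- ds$records[[ds$alignment$reference_id]]
  part <- detect_partition(rec$sequence)
  ann <- suppressWarnings(annotate_regions(rec))
  snps <- call_snps(ds$alignment, "PLAN1", part, ann)
  indels <- call_indels(ds$alignment, "PLAN1", part, ann)
  prefix <- tempfile()
  paths <- write_variant_tables(snps, indels, prefix, rec$accession)
  back <- read_snp_vcf(paths[["vcf"]])
  ord <- order(snps$ref_pos, snps$accession)
  expect_equal(back$ref_pos, snps$ref_pos[ord])
  expect_equal(back$ref_allele, snps$ref_allele[ord])
  expect_equal(back$alt_allele, snps$alt_allele[ord])
  expect_equal(back$ts_tv, snps$ts_tv[ord])
  # structural lint: sorted positions, REF matches the reference sequence
  expect_true(!is.unsorted(back$ref_pos))
  ref_chars <- strsplit(rec$sequence, "")[[1]]
  expect_true(all(ref_chars[back$ref_pos] == back$ref_allele))

  # empty sets give valid header-only files
  p2 <- write_variant_tables(snps[0, ], indels[0, ], tempfile(), rec$accession)
  expect_equal(nrow(read_snp_vcf(p2[["vcf"]])), 0L)
  expect_true(file.exists(p2[["indels"]]))
})

test_that("SNP at reference position 1 is written as VCF POS 1", {
  snp <- data.frame(accession = "q", ref_pos = 1L, ref_allele = "A",
                    alt_allele = "G", ts_tv = "Ts",
                    structural_region = "LSC", functional_region = "IGS",
                    locus = "x", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_snp_vcf(snp, path, "REF1")
  body <- grep("^[^#]", readLines(path), value = TRUE)
  expect_equal(strsplit(body, "\t")[[1]][2], "1")
})
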