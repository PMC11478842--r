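# End-to-end orchestration: structure -> variation -> repeats -> codon usage /
# Ka-Ks -> diagnostic marker design, writing one report directory of TSV /
# VCF / BED tables mirroring the layout of the source tables.

#' Pipeline configuration
#'
#' @param records named list of [plastome_record()]s, or a character vector
#'   of GenBank file paths (read with [read_genbank()])
#' @param alignment a [plast_alignment()], or the path to an aligned FASTA
#'   (then `species_map` must be the TSV path)
#' @param species_map species-map TSV path when `alignment` is a path
#' @param reference_id reference accession
#' @param target_species target species for the diagnostic-marker stage
#' @param out_dir report directory
#' @param stages character vector of stages to run (subset of "structure",
#'   "variation", "repeats", "codon", "barcode")
#' @param window,step window parameters for [window_pi()]
#' @param hotspot_k number of hotspots to report
#' @param constraints primer constraints ([primer_constraints()])
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(records, alignment, species_map = NULL,
                            reference_id, target_species = NULL,
                            out_dir = "plastomarker_report",
                            stages = c("structure", "variation", "repeats",
                                       "codon", "barcode"),
                            window = 100L, step = window, hotspot_k = 20L,
                            constraints = primer_constraints(), seed = 1L) {
  unknown <- setdiff(stages, c("structure", "variation", "repeats", "codon", "barcode"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  structure(list(records = records, alignment = alignment,
                 species_map = species_map, reference_id = reference_id,
                 target_species = target_species, out_dir = out_dir,
                 stages = stages, window = window, step = step,
                 hotspot_k = hotspot_k, constraints = constraints, seed = seed),
            class = "pipeline_config")
}

#' Run the comparative-plastomics pipeline
#'
#' Runs the enabled stages in order on all input genomes and writes
#' `table1_structure.tsv`, `table3_substitutions.tsv`, `table4_indels.tsv`,
#' `table5_hotspots.tsv`, `kaks.tsv`, `ssr.tsv`, `repeats.tsv`, `tandem.tsv`,
#' `junctions.tsv`, `window_pi.tsv`, `diagnostic_snps.vcf`, `primers.tsv`,
#' per-accession partition BEDs and a JSON run manifest into the report
#' directory. A stage failure halts with a stage-tagged error; outputs of
#' completed stages are retained. Identical config and inputs reproduce
#' identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return named list of result tables, invisibly; side effect: the report
#'   directory
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  records <- config$records
  if (is.character(records)) {
    records <- lapply(records, read_genbank)
    names(records) <- vapply(records, `[[`, "", "accession")
  }
  aln <- config$alignment
  if (is.character(aln)) {
    aln <- read_alignment(aln, config$species_map, config$reference_id)
  }
  ref_rec <- records[[config$reference_id]]
  if (is.null(ref_rec)) stop("reference record not among input records: ",
                             config$reference_id)
  results <- list()

  partitions <- stage("structure", lapply(records, function(r) {
    tryCatch(detect_partition(r$sequence), noIRFound = function(e) NULL)
  }))
  annotation <- annotate_regions(ref_rec)
  ref_part <- partitions[[config$reference_id]]

  if ("structure" %in% config$stages) {
    stage("structure", {
      rows <- lapply(names(records), function(acc) {
        r <- records[[acc]]; p <- partitions[[acc]]
        gcs <- if (!is.null(p)) region_gc(r, p) else NULL
        gsum <- gene_content_summary(r, p)
        data.frame(
          accession = acc, species = r$species, size = r$length,
          lsc = if (!is.null(p)) p$lsc_length else NA_integer_,
          ssc = if (!is.null(p)) p$ssc_length else NA_integer_,
          ir = if (!is.null(p)) p$ir_length else NA_integer_,
          gc_total = if (!is.null(gcs)) gcs$gc[gcs$region == "total"] else NA_real_,
          gc_lsc = if (!is.null(gcs)) gcs$gc[gcs$region == "LSC"] else NA_real_,
          gc_ssc = if (!is.null(gcs)) gcs$gc[gcs$region == "SSC"] else NA_real_,
          gc_ir = if (!is.null(gcs)) gcs$gc[gcs$region == "IRb"] else NA_real_,
          n_genes = gsum$n_unique_genes, n_ir_duplicated = gsum$n_ir_duplicated,
          stringsAsFactors = FALSE)
      })
      results$structure <- do.call(rbind, rows)
      utils::write.table(results$structure, file.path(out, "table1_structure.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (acc in names(records)) {
        if (!is.null(partitions[[acc]]))
          write_partition_bed(partitions[[acc]], acc,
                              file.path(out, paste0(acc, "_partition.bed")))
      }
      results$junctions <- junction_report(unname(records), unname(partitions))
      utils::write.table(results$junctions, file.path(out, "junctions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  if ("variation" %in% config$stages) {
    stage("variation", {
      queries <- setdiff(rownames(aln$matrix), config$reference_id)
      snps <- do.call(rbind, lapply(queries, function(q)
        call_snps(aln, q, ref_part, annotation)))
      indels <- do.call(rbind, lapply(queries, function(q)
        call_indels(aln, q, ref_part, annotation)))
      write_variant_tables(snps, indels, file.path(out, "variants"),
                           config$reference_id)
      file.copy(file.path(out, "variants_substitution_summary.tsv"),
                file.path(out, "table3_substitutions.tsv"), overwrite = TRUE)
      file.copy(file.path(out, "variants_indel_summary.tsv"),
                file.path(out, "table4_indels.tsv"), overwrite = TRUE)
      results$snps <- snps
      results$indels <- indels
      wp <- window_pi(aln, window = config$window, step = config$step)
      utils::write.table(wp, file.path(out, "window_pi.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$window_pi <- wp
      lp <- locus_pi(aln, annotation)
      hs <- rank_hotspots(lp, k = config$hotspot_k)
      utils::write.table(hs, file.path(out, "table5_hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$hotspots <- hs
      results$p_distance <- pairwise_p_distance(aln)
      results$intraspecific <- intraspecific_diversity(aln)
    })
  }

  if ("repeats" %in% config$stages) {
    stage("repeats", {
      ssr_all <- list(); disp_all <- list(); tand_all <- list()
      for (acc in names(records)) {
        r <- records[[acc]]; p <- partitions[[acc]]
        ann <- if (acc == config$reference_id) annotation else annotate_regions(r)
        ssr <- find_ssrs(r$sequence, circular = TRUE)
        if (nrow(ssr)) ssr_all[[acc]] <- cbind(accession = acc,
                                               attribute_repeats(ssr, p, ann))
        disp <- find_dispersed_repeats(r$sequence)
        if (nrow(disp)) {
          occ <- attribute_repeats(dispersed_occurrences(disp), p, ann)
          disp_all[[acc]] <- cbind(accession = acc, occ)
        }
        tand <- find_tandem_repeats(r$sequence)
        if (nrow(tand)) tand_all[[acc]] <- cbind(accession = acc,
                                                 attribute_repeats(tand, p, ann))
      }
      results$ssr <- do.call(rbind, ssr_all)
      results$dispersed <- do.call(rbind, disp_all)
      results$tandem <- do.call(rbind, tand_all)
      utils::write.table(results$ssr %||% data.frame(), file.path(out, "ssr.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(results$dispersed %||% data.frame(),
                         file.path(out, "repeats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(results$tandem %||% data.frame(),
                         file.path(out, "tandem.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  if ("codon" %in% config$stages) {
    stage("codon", {
      cds <- vapply(Filter(function(f) f$kind == "CDS", ref_rec$features),
                    function(f) feature_sequence(ref_rec, f), "")
      results$rscu <- suppressWarnings(rscu(cds))
      utils::write.table(results$rscu$rscu, file.path(out, "rscu.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      queries <- setdiff(rownames(aln$matrix), config$reference_id)
      kk <- do.call(rbind, lapply(queries, function(q)
        cbind(accession = q, kaks_table(aln, q, ref_rec))))
      results$kaks <- kk
      utils::write.table(kk, file.path(out, "kaks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  if ("barcode" %in% config$stages && !is.null(config$target_species)) {
    stage("barcode", {
      snps <- find_diagnostic_snps(aln, config$target_species)
      results$diagnostic_snps <- snps
      vcf_ready <- data.frame(
        accession = rep(config$target_species, nrow(snps)),
        ref_pos = ifelse(is.na(snps$ref_pos), snps$column, snps$ref_pos),
        ref_allele = snps$background_alleles,
        alt_allele = snps$target_allele,
        ts_tv = NA_character_, structural_region = NA_character_,
        functional_region = NA_character_, locus = NA_character_,
        stringsAsFactors = FALSE)
      # VCF REF must be a single base; use the reference row's base
      vcf_ready$ref_allele <- aln$matrix[aln$reference_id, snps$column]
      vcf_ready <- vcf_ready[!is.na(snps$ref_pos), , drop = FALSE]
      vcf_ready$ts_tv <- classify_substitution(vcf_ready$ref_allele,
                                               vcf_ready$alt_allele)
      write_snp_vcf(vcf_ready, file.path(out, "diagnostic_snps.vcf"),
                    config$reference_id)
      pairs <- design_diagnostic_pair(aln, snps, config$constraints)
      ctrl <- tryCatch(design_control_pair(aln, config$constraints),
                       error = function(e) NULL)
      primers <- rbind(pairs, ctrl)
      results$primers <- primers
      utils::write.table(primers %||% data.frame(), file.path(out, "primers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(primers) && nrow(primers)) {
        amp <- do.call(rbind, lapply(names(records), function(acc) {
          do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
            a <- in_silico_pcr(records[[acc]], primers[i, ])
            if (!nrow(a)) return(NULL)
            cbind(accession = acc, pair = i, role = primers$role[i], a)
          }))
        }))
        results$amplicons <- amp
        utils::write.table(amp %||% data.frame(), file.path(out, "amplicons.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  manifest <- list(
    package = "plastomarker",
    version = as.character(utils::packageVersion("plastomarker")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    reference_id = config$reference_id,
    target_species = config$target_species,
    stages = config$stages,
    parameters = list(window = config$window, step = config$step,
                      hotspot_k = config$hotspot_k,
                      constraints = config$constraints),
    seed = config$seed,
    accessions = names(records)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
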