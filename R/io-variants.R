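# Variant table output: SNPs as a minimal VCF v4.2 (CHROM = reference
# accession, 1-based POS on the reference, INFO carries Ts/Tv classing, the
# query accession and region attribution), indels and summary tables as TSV.

#' Write SNP and indel tables
#'
#' SNP records go to `<prefix>_snps.vcf` (sorted by position on write), indel
#' records to `<prefix>_indels.tsv`, and per-accession substitution / indel
#' summaries to `<prefix>_substitution_summary.tsv` and
#' `<prefix>_indel_summary.tsv`.
#'
#' @param snps data.frame as returned by [call_snps()] (possibly rbind-ed over
#'   accessions); may be empty
#' @param indels data.frame as returned by [call_indels()]; may be empty
#' @param out_prefix path prefix for the four output files
#' @param reference_id reference accession written to the CHROM column
#' @return named character vector of the written paths, invisibly
#' @export
write_variant_tables <- function(snps, indels, out_prefix, reference_id) {
  paths <- c(
    vcf = paste0(out_prefix, "_snps.vcf"),
    indels = paste0(out_prefix, "_indels.tsv"),
    subst = paste0(out_prefix, "_substitution_summary.tsv"),
    indel_summary = paste0(out_prefix, "_indel_summary.tsv")
  )
  write_snp_vcf(snps, paths[["vcf"]], reference_id)

  cols <- c("accession", "ref_pos", "length", "kind", "structural_region", "locus")
  if (!nrow(indels)) {
    indels <- data.frame(accession = character(0), ref_pos = integer(0),
                         length = integer(0), kind = character(0),
                         structural_region = character(0), locus = character(0))
  }
  indels <- indels[order(indels$ref_pos), cols, drop = FALSE]
  utils::write.table(indels, paths[["indels"]], sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(substitution_summary(snps), paths[["subst"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(indel_summary(indels), paths[["indel_summary"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write SNP records as a minimal VCF v4.2
#'
#' @inheritParams write_variant_tables
#' @param path output path
#' @return `path`, invisibly
#' @export
write_snp_vcf <- function(snps, path, reference_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", reference_id),
    "##INFO=<ID=ACC,Number=1,Type=String,Description=\"Query accession carrying the alternate allele\">",
    "##INFO=<ID=TSTV,Number=1,Type=String,Description=\"Substitution class: Ts or Tv\">",
    "##INFO=<ID=SREG,Number=1,Type=String,Description=\"Structural region: LSC, SSC or IR\">",
    "##INFO=<ID=FREG,Number=1,Type=String,Description=\"Functional region: CDS, intron or IGS\">",
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"Locus name\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (!is.null(snps) && nrow(snps)) {
    snps <- snps[order(snps$ref_pos, snps$accession), , drop = FALSE]
    info <- sprintf("ACC=%s;TSTV=%s;SREG=%s;FREG=%s;LOCUS=%s",
                    snps$accession, snps$ts_tv,
                    snps$structural_region %||% NA, snps$functional_region %||% NA,
                    snps$locus %||% NA)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                       reference_id, snps$ref_pos, snps$ref_allele,
                       snps$alt_allele, info), con)
  }
  invisible(path)
}

#' Read a minimal SNP VCF written by [write_snp_vcf()]
#'
#' @param path VCF path
#' @return data.frame with the [call_snps()] columns
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(accession = character(0), ref_pos = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      ts_tv = character(0), structural_region = character(0),
                      functional_region = character(0), locus = character(0))
  if (!length(body)) return(empty)
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    out[m != ""] <- sub(paste0("^;?", key, "="), "", m[m != ""])
    out
  }
  info <- fields[, 8L]
  data.frame(
    accession = info_get(info, "ACC"),
    ref_pos = as.integer(fields[, 2L]),
    ref_allele = fields[, 4L],
    alt_allele = fields[, 5L],
    ts_tv = info_get(info, "TSTV"),
    structural_region = info_get(info, "SREG"),
    functional_region = info_get(info, "FREG"),
    locus = info_get(info, "LOCUS"),
    stringsAsFactors = FALSE
  )
}

#' Per-accession substitution summary (Table 3 layout)
#'
#' Counts of each unordered substitution class (A/G, C/T, A/C, A/T, C/G, G/T),
#' transition and transversion totals and the Ts/Tv ratio, one row per query
#' accession.
#'
#' @param snps SNP data.frame from [call_snps()]
#' @return data.frame
#' @export
substitution_summary <- function(snps) {
  classes <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  if (is.null(snps) || !nrow(snps)) {
    out <- data.frame(accession = character(0))
    for (cl in classes) out[[cl]] <- integer(0)
    out$Ts <- integer(0); out$Tv <- integer(0); out$ts_tv_ratio <- numeric(0)
    out$total <- integer(0)
    return(out)
  }
  pair <- apply(cbind(snps$ref_allele, snps$alt_allele), 1L,
                function(x) paste(sort(x), collapse = "/"))
  do.call(rbind, lapply(split(seq_len(nrow(snps)), snps$accession), function(idx) {
    counts <- table(factor(pair[idx], levels = classes))
    ts <- sum(snps$ts_tv[idx] == "Ts")
    tv <- sum(snps$ts_tv[idx] == "Tv")
    out <- data.frame(accession = snps$accession[idx[1L]], stringsAsFactors = FALSE)
    for (cl in classes) out[[cl]] <- as.integer(counts[[cl]])
    out$Ts <- ts
    out$Tv <- tv
    out$ts_tv_ratio <- if (tv > 0L) ts / tv else NA_real_
    out$total <- length(idx)
    out
  }))
}

#' Per-accession, per-region indel summary (Table 4 layout)
#'
#' @param indels indel data.frame from [call_indels()]
#' @return data.frame with event counts, total bases and mean length per
#'   accession and structural region
#' @export
indel_summary <- function(indels) {
  if (is.null(indels) || !nrow(indels)) {
    return(data.frame(accession = character(0), structural_region = character(0),
                      events = integer(0), bases = integer(0), mean_length = numeric(0)))
  }
  key <- paste(indels$accession, indels$structural_region, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(indels)), key), function(idx) {
    data.frame(accession = indels$accession[idx[1L]],
               structural_region = indels$structural_region[idx[1L]],
               events = length(idx),
               bases = sum(indels$length[idx]),
               mean_length = mean(indels$length[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$accession, out$structural_region), , drop = FALSE]
}
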