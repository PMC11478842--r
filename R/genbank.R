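# Minimal GenBank flat-file reader/writer. No installed R package parses
# GenBank flat files in this stack, so the subset the pipeline touches
# (single circular DNA record; CDS/tRNA/rRNA features with join/complement
# locations; /gene and /pseudo qualifiers; ORIGIN block) is handled here.

#' Read a GenBank flat file into a plastome record
#'
#' Parses a single-record GenBank flat file. Feature keys CDS, tRNA and rRNA
#' are captured (a `/pseudo` qualifier reclassifies a copy as "pseudogene");
#' `gene` and `source` keys are skipped silently as they duplicate captured
#' information, any other key is skipped with a warning. `join(...)` and
#' `complement(...)` locations are decomposed into ordered parts.
#'
#' @param path path to a GenBank flat file
#' @return a [plastome_record()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)

  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path)
  accession <- NA_character_
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    accession <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1L]])), "\\s+")[[1L]][1L]
  }
  if (is.na(accession) || !nzchar(accession)) {
    accession <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1L]])), "\\s+")[[1L]][1L]
  }
  species <- ""
  org_i <- grep("^\\s{2}ORGANISM", lines)
  if (length(org_i)) species <- trimws(sub("^\\s+ORGANISM", "", lines[org_i[1L]]))

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("GenBank record has no ORIGIN sequence block: ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1L] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty sequence: ", path)

  features <- list()
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i)) {
    block <- lines[(feat_i[1L] + 1L):(origin_i[1L] - 1L)]
    key_rows <- grep("^ {5}\\S", block)
    skipped <- character(0)
    for (ki in seq_along(key_rows)) {
      from <- key_rows[ki]
      to <- if (ki < length(key_rows)) key_rows[ki + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
      body <- trimws(sub("^ {5}\\S+\\s*", "", chunk[1L]))
      rest <- trimws(chunk[-1L])
      # location may continue over lines until the first qualifier
      qual_start <- which(startsWith(rest, "/"))
      loc_extra <- if (length(qual_start)) rest[seq_len(qual_start[1L] - 1L)] else rest
      quals <- if (length(qual_start)) rest[qual_start[1L]:length(rest)] else character(0)
      location <- paste0(body, paste(loc_extra, collapse = ""))
      if (key %in% c("source", "gene")) next
      if (!key %in% c("CDS", "tRNA", "rRNA")) {
        skipped <- c(skipped, key)
        next
      }
      kind <- key
      if (any(grepl("^/pseudo\\b", quals))) kind <- "pseudogene"
      name <- .gb_qualifier(quals, "gene") %||%
        .gb_qualifier(quals, "locus_tag") %||%
        .gb_qualifier(quals, "product") %||% key
      loc <- .parse_location(location)
      features[[length(features) + 1L]] <-
        gene_feature(name, kind, loc$strand, loc$parts, wraps = loc$wraps)
    }
    if (length(skipped)) {
      plast_warning(sprintf("skipped %d feature(s) of unhandled kind(s): %s",
                            length(skipped), paste(unique(skipped), collapse = ", ")))
    }
  }

  plastome_record(accession, species, sequence, features)
}

#' @keywords internal
.gb_qualifier <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NULL)
  gsub("\"", "", sub(paste0("^/", what, "="), "", hit[1L]))
}

# Parse a GenBank location string into 1-based closed parts plus strand.
# Handles a..b, complement(...), join(...), order(...), partial markers <,>.
#' @keywords internal
.parse_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  bits <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  parts <- t(vapply(bits, function(b) {
    b <- sub("^complement\\((.*)\\)$", "\\1", b)  # per-part complement: strand kept feature-wide
    if (grepl("\\.\\.", b)) {
      as.integer(strsplit(b, "..", fixed = TRUE)[[1L]][c(1L, 2L)])
    } else {
      rep(as.integer(b), 2L)
    }
  }, integer(2)))
  colnames(parts) <- c("start", "end")
  wraps <- FALSE
  if (nrow(parts) > 1L) {
    # a final part restarting at 1 after a part ending anywhere signals an
    # origin-wrapping feature written as join(x..N,1..y)
    if (parts[1L, "start"] > parts[nrow(parts), "start"]) wraps <- TRUE
  }
  list(strand = strand, parts = parts, wraps = wraps)
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits the minimal subset [read_genbank()] consumes: LOCUS/ACCESSION/
#' ORGANISM headers, CDS/tRNA/rRNA features with join/complement locations and
#' `/gene` qualifiers (`/pseudo` for pseudogene copies), and the ORIGIN block.
#'
#' @param record a [plastome_record()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     circular PLN %s",
     record$accession, record$length, format(Sys.Date(), "%d-%b-%Y"))
  wl("DEFINITION  %s chloroplast, complete genome.", record$species)
  wl("ACCESSION   %s", record$accession)
  wl("SOURCE      %s", record$species)
  wl("  ORGANISM  %s", record$species)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", record$length)
  for (f in record$features) {
    spans <- apply(f$parts, 1L, function(p)
      if (p[1L] == p[2L]) as.character(p[1L]) else sprintf("%d..%d", p[1L], p[2L]))
    loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind == "pseudogene") "CDS" else f$kind
    wl("     %-16s%s", key, loc)
    wl("                     /gene=\"%s\"", f$name)
    if (f$kind == "pseudogene") wl("                     /pseudo")
  }
  wl("ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl("%9d %s", p, paste(tens, collapse = " "))
  }
  wl("//")
  invisible(path)
}
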