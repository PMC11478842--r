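# Shared fixtures: a desk-scale simulation configuration and a lazily built,
# cached dataset reused across test files (regenerating it per test would
# dominate the suite's runtime).

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 101L, ...) {
  simulation_config(
    seed = seed,
    lsc_length = 11000L, ir_length = 3500L, ssc_length = 4000L,
    diagnostic = list(species = "Plantago lanceolata", n = 8L,
                      pair_spacing = 900L),
    ir_expansion = list(accession = "PMAR1", bp = 1500L),
    ...
  )
}

small_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    .fixture_cache$ds <- simulate_plastome_family(small_config())
  }
  .fixture_cache$ds
}

rand_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# tiny helper to build an alignment matrix from equal-length strings
make_alignment <- function(rows, species = NULL, reference_id = names(rows)[1]) {
  mat <- do.call(rbind, strsplit(unlist(rows), ""))
  rownames(mat) <- names(rows)
  if (is.null(species)) {
    species <- stats::setNames(paste("sp", seq_along(rows)), names(rows))
  }
  plast_alignment(mat, species, reference_id)
}
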