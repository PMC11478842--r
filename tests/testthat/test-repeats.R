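# Repeat finders against brute-force oracles, plus threshold semantics.

# ---- independent oracles ----------------------------------------------------

# every (start, period) pair tested directly against the definition
oracle_ssrs <- function(sequence, thresholds = c(`1` = 7L, `2` = 4L, `3` = 3L,
                                                 `4` = 3L, `5` = 3L, `6` = 3L)) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  base <- s %in% c("A", "C", "G", "T")
  out <- list()
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    for (a in seq_len(max(0, n - p * thr + 1))) {
      if (a > 1 && a + p - 1 <= n && base[a - 1] && base[a + p - 1] &&
          s[a - 1] == s[a + p - 1]) next  # left-extendable
      m <- 0L
      t <- 0L
      while (a + t <= n && base[a + t] && s[a + t] == s[a + (t %% p)]) t <- t + 1L
      m <- t %/% p
      if (m < thr) next
      motif <- s[a:(a + p - 1)]
      periodic <- FALSE
      for (q in seq_len(p - 1)) {
        if (p %% q == 0 && all(motif == rep_len(motif[1:q], p))) periodic <- TRUE
      }
      if (periodic) next
      out[[length(out) + 1L]] <- data.frame(start = a, unit_len = p, copies = m)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), unit_len = integer(0),
                                      copies = integer(0)))
  unique(do.call(rbind, out))
}

# all-diagonals scan for dispersed repeats, naive implementation
oracle_dispersed <- function(sequence, min_len = 30L, max_mismatch = 3L) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  windows_of <- function(v) {
    mp <- which(!v); r <- length(mp); L <- length(v)
    if (L == 0) return(NULL)
    spans <- list()
    if (r <= max_mismatch) {
      spans[[1]] <- c(1L, L)
    } else {
      for (g in 0:(r - max_mismatch)) {
        lo <- if (g == 0) 1L else mp[g] + 1L
        hi <- if (g + max_mismatch + 1 > r) L else mp[g + max_mismatch + 1] - 1L
        spans[[length(spans) + 1L]] <- c(lo, hi)
      }
    }
    out <- NULL
    for (sp in spans) {
      a <- sp[1]; b <- sp[2]
      while (a <= b && !v[a]) a <- a + 1
      while (b >= a && !v[b]) b <- b - 1
      if (b >= a && b - a + 1 >= min_len) out <- rbind(out, c(a, b, sum(!v[a:b])))
    }
    unique(out)
  }
  rows <- list()
  add <- function(kind, a1, b1, a2, b2, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, start1 = a1, end1 = b1, start2 = a2, end2 = b2,
      length = b1 - a1 + 1L, mismatches = mm, stringsAsFactors = FALSE)
  }
  for (d in seq_len(n - 1)) {  # F and C diagonals
    i <- seq_len(n - d)
    okF <- s[i] == s[i + d] & s[i] != "N" & s[i + d] != "N"
    for (w in seq_len(NROW(windows_of(okF)))) {
      win <- windows_of(okF)[w, , drop = TRUE]
      add("F", win[1], win[2], win[1] + d, win[2] + d, win[3])
    }
    okC <- s[i] == comp[s[i + d]] & s[i] != "N" & s[i + d] != "N"
    for (w in seq_len(NROW(windows_of(okC)))) {
      win <- windows_of(okC)[w, , drop = TRUE]
      add("C", win[1], win[2], win[1] + d, win[2] + d, win[3])
    }
  }
  for (cc in 3:(2 * n - 1)) {  # P and R anti-diagonals
    amin <- max(1L, cc - n); amax <- (cc - 1L) %/% 2L
    if (amax < amin) next
    a <- seq.int(amin, amax)
    okP <- s[a] == comp[s[cc - a]] & s[a] != "N" & s[cc - a] != "N"
    wp <- windows_of(okP)
    for (w in seq_len(NROW(wp))) {
      win <- wp[w, , drop = TRUE] + c(amin - 1L, amin - 1L, 0L)
      add("P", win[1], win[2], cc - win[2], cc - win[1], win[3])
    }
    okR <- s[a] == s[cc - a] & s[a] != "N" & s[cc - a] != "N"
    wr <- windows_of(okR)
    for (w in seq_len(NROW(wr))) {
      win <- wr[w, , drop = TRUE] + c(amin - 1L, amin - 1L, 0L)
      add("R", win[1], win[2], cc - win[2], cc - win[1], win[3])
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0), length = integer(0),
               mismatches = integer(0))
  # same nesting suppression as the implementation's contract
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (i == j || !keep[j]) next
      if (calls$kind[i] == calls$kind[j] && calls$length[j] < calls$length[i] &&
          calls$start1[j] >= calls$start1[i] && calls$end1[j] <= calls$end1[i] &&
          calls$start2[j] >= calls$start2[i] && calls$end2[j] <= calls$end2[i]) {
        keep[j] <- FALSE
      }
    }
  }
  calls[keep, , drop = FALSE]
}

repeat_key <- function(df) {
  sort(paste(df$kind, df$start1, df$end1, df$start2, df$end2))
}

# ---- SSR tests --------------------------------------------------------------

test_that("SSR thresholds follow the 7/4/3 rule", {
  expect_equal(nrow(find_ssrs("AAAAAAA")), 1L)   # 7xA reported
  expect_equal(nrow(find_ssrs("AAAAAA")), 0L)    # 6xA not reported
  di <- find_ssrs("ATATATAT")
  expect_equal(nrow(di), 1L)
  expect_equal(di$copies, 4L)
  expect_equal(di$motif, "AT")                   # canonical minimal rotation
  expect_equal(find_ssrs("TATATATA")$motif, "AT")
  expect_equal(nrow(find_ssrs("ATATAT")), 0L)    # 3 copies of dinucleotide
  tri <- find_ssrs("AATAATAAT")
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$unit_len, 3L)
})

test_that("homopolymer runs are not re-reported at larger periods", {
  calls <- find_ssrs(paste0("GC", strrep("A", 12), "GC"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$unit_len, 1L)
  expect_equal(calls$copies, 12L)
})

test_that("Ns break SSR runs", {
  expect_equal(nrow(find_ssrs("AAAANAAAA")), 0L)
  expect_equal(nrow(find_ssrs(paste0("AAAAAAAN", "AAAAAAA"))), 2L)
})

test_that("SSR calls equal the brute-force oracle on fuzzed sequences", {
  set.seed(55)
  for (rep in 1:12) {
    # AT-rich to provoke runs, plus planted SSRs
    sq <- paste0(rand_seq(300, gc = 0.2), strrep("AT", 5), rand_seq(100, gc = 0.2),
                 strrep("TTA", 4), rand_seq(200, gc = 0.2))
    got <- find_ssrs(sq)
    want <- oracle_ssrs(sq)
    expect_equal(nrow(got), nrow(want), info = paste("rep", rep))
    expect_setequal(paste(got$start, got$unit_len, got$copies),
                    paste(want$start, want$unit_len, want$copies))
  }
})

test_that("circular SSR scan catches an origin-spanning run once", {
  sq <- paste0("AAAA", rand_seq(200, gc = 0.6), "AAAA")
  lin <- find_ssrs(sq)
  circ <- find_ssrs(sq, circular = TRUE)
  mono <- circ[circ$unit_len == 1 & circ$motif == "A", ]
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$copies, 8L)
  expect_equal(nrow(lin[lin$unit_len == 1 & lin$motif == "A", ]), 0L)
})

# ---- dispersed repeats ------------------------------------------------------

test_that("planted forward and palindromic copies are found exactly", {
  set.seed(20)
  base <- rand_seq(2500)
  seg <- substr(base, 201, 240)
  sq <- paste0(substr(base, 1, 800), seg, substr(base, 801, 1600),
               revcomp(seg), substr(base, 1601, 2500))
  calls <- find_dispersed_repeats(sq)
  fcalls <- calls[calls$kind == "F" & calls$length >= 40, ]
  pcalls <- calls[calls$kind == "P" & calls$length >= 40, ]
  expect_gte(nrow(fcalls), 1L)
  expect_gte(nrow(pcalls), 1L)
  # the planted F pair appears with zero-mismatch core covering the segment
  expect_true(any(fcalls$start1 <= 201 & fcalls$end1 >= 240))
})

test_that("dispersed calls equal the quadratic oracle on fuzzed sequences", {
  set.seed(66)
  for (rep in 1:6) {
    base <- rand_seq(400)
    seg <- substr(base, 51, 85)
    # plant a forward copy with one mismatch and a revcomp copy
    seg_mut <- seg
    substr(seg_mut, 17, 17) <- setdiff(c("A", "C", "G", "T"),
                                       substr(seg, 17, 17))[1]
    sq <- paste0(base, seg_mut, rand_seq(120), revcomp(seg))
    got <- find_dispersed_repeats(sq, seed_len = 7L)
    want <- oracle_dispersed(sq)
    expect_equal(repeat_key(got), repeat_key(want), info = paste("rep", rep))
  }
})

test_that("swapping occurrences leaves the F/P classification invariant", {
  calls <- find_dispersed_repeats(
    paste0(rand_seq(200), strrep("ACGTTGCA", 5), rand_seq(200),
           strrep("ACGTTGCA", 5)), seed_len = 7L)
  # canonical ordering start1 <= start2 always holds
  expect_true(all(calls$start1 <= calls$start2))
})

test_that("results are capped by descending length", {
  set.seed(88)
  sq <- paste(rep(rand_seq(60), 12), collapse = "")  # many nested repeats
  capped <- find_dispersed_repeats(sq, max_results = 5, seed_len = 7L)
  expect_lte(nrow(capped), 5L)
  expect_true(!is.unsorted(rev(capped$length)))
})

# ---- tandem repeats ---------------------------------------------------------

test_that("planted tandem arrays are detected with correct period", {
  set.seed(3)
  motif <- rand_seq(30)
  sq <- paste0(rand_seq(400), strrep(motif, 3), rand_seq(400))
  calls <- find_tandem_repeats(sq)
  expect_gte(nrow(calls), 1L)
  hit <- calls[which.max(calls$span), ]
  expect_equal(hit$period, 30L)
  expect_gte(hit$copies, 2.5)
  # array covered by the call
  expect_lte(hit$start, 401 + 30)
  expect_gte(hit$end, 401 + 60)
})

test_that("tandem arrays survive 10% per-copy mutation", {
  set.seed(4)
  motif <- rand_seq(40)
  mutate <- function(m, k) {
    ch <- strsplit(m, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- sapply(ch[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1))
    paste(ch, collapse = "")
  }
  arr <- paste0(motif, mutate(motif, 4), motif, mutate(motif, 4))
  sq <- paste0(rand_seq(300), arr, rand_seq(300))
  calls <- find_tandem_repeats(sq)
  expect_gte(nrow(calls), 1L)
  hit <- calls[which.max(calls$span), ]
  expect_equal(hit$period, 40L)
})

test_that("every tandem call satisfies its own span/period invariant", {
  set.seed(9)
  for (rep in 1:4) {
    sq <- paste0(rand_seq(800), strrep(rand_seq(25), 3), rand_seq(200))
    calls <- find_tandem_repeats(sq)
    if (!nrow(calls)) next
    expect_equal(calls$span, calls$end - calls$start + 1L)
    expect_equal(calls$copies, calls$span / calls$period)
    expect_true(all(calls$period >= 7L))
    # the growth guarantee: disagreements / (window + period) <= 0.2
    mism <- (1 - calls$identity) * (calls$span - calls$period)
    expect_true(all(mism / calls$span <= 0.2 + 1e-9))
  }
})

# ---- attribution ------------------------------------------------------------

test_that("repeat attribution assigns regions by midpoint and conserves totals", {
  part <- structure(list(lsc = c(1L, 400L), irb = c(401L, 600L),
                         ssc = c(601L, 800L), ira = c(801L, 1000L),
                         lsc_length = 400L, ir_length = 200L, ssc_length = 200L,
                         genome_length = 1000L),
                    class = "quadripartite_partition")
  rec <- plastome_record("A", "sp", rand_seq(1000), list(
    gene_feature("g1", "CDS", "+", cbind(100L, 200L))
  ))
  ann <- annotate_regions(rec)
  calls <- data.frame(start = c(120L, 395L, 700L, 950L),
                      end = c(140L, 420L, 720L, 990L))
  out <- attribute_repeats(calls, part, ann)
  expect_equal(out$structural_region, c("LSC", "IR", "SSC", "IR"))
  expect_equal(out$functional_region[1], "CDS")
  expect_equal(out$functional_region[3], "IGS")
  expect_true(out$straddles_junction[2])   # spans the LSC/IRb boundary
  expect_equal(sum(attr(out, "structural_counts")), nrow(calls))
})
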