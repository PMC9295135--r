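test_that("mapping-quality filtering keeps >=30 and drops below", {
  recs <- random_paf_records(2)[c(1, 1), ]
  recs$qname <- "r1"
  recs$mapq <- c(29L, 30L)
  sr <- filter_subreads(recs, caller_params())
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$mapq, 30L)

  set.seed(3)
  recs <- random_paf_records(300)
  recs$mapq <- sample(0:60, 300, replace = TRUE)
  sr <- filter_subreads(recs, caller_params())
  expect_equal(nrow(sr), sum(recs$mapq >= 30))  # brute-force count

  recs$mapq <- 60L
  sr <- filter_subreads(recs, caller_params())
  expect_equal(nrow(sr), 300L)
  expect_true(all(tapply(sr$qstart, sr$qname, function(q) !is.unsorted(q))))
})

test_that("locus clustering honours the 20 bp start/end offset", {
  sr <- make_sr(c(1000L, 1020L), c(1900L, 1920L))
  expect_equal(cluster_loci(sr, caller_params())$labels, c(1L, 1L))
  sr <- make_sr(c(1000L, 1021L), c(1900L, 1920L))
  expect_equal(cluster_loci(sr, caller_params())$labels, c(1L, 2L))

  sr <- make_sr(rep(5000L, 5), rep(5800L, 5))
  cl <- cluster_loci(sr, caller_params())
  expect_equal(cl$labels, rep(1L, 5))
  expect_equal(cl$clusters$size, 5L)

  # strand and chromosome both separate clusters
  sr <- make_sr(c(1000L, 1000L), c(1900L, 1900L), strand = c("+", "-"))
  expect_equal(cluster_loci(sr, caller_params())$labels, c(1L, 2L))
})

test_that("clustering matches the brute-force oracle under bounded jitter", {
  set.seed(11)
  for (rep in 1:200) {
    J <- sample(0:20, 1)
    n_loci <- sample(1:3, 1)
    base_start <- sample(seq(1000L, 90000L, by = 2000L), n_loci)
    base_end <- base_start + sample(200:800, n_loci, replace = TRUE)
    n <- sample(2:9, 1)
    pick <- sample(n_loci, n, replace = TRUE)
    start <- base_start[pick] + sample(-J:J, n, replace = TRUE)
    end <- base_end[pick] + sample(-J:J, n, replace = TRUE)
    sr <- make_sr(start, end)
    got <- cluster_loci(sr, caller_params())$labels
    expect_equal(got, bf_cluster(sr$tname, sr$strand, start, end, 20L))
  }
})

test_that("cyclic concordance accepts periodic label sequences only", {
  r <- check_concordance(c("A", "B", "C", "A", "B", "C", "A"))
  expect_true(r$accepted)
  expect_equal(r$cycle, c("A", "B", "C"))

  r <- check_concordance(c("A", "A", "A"))
  expect_true(r$accepted)
  expect_equal(r$cycle, "A")

  r <- check_concordance(c("A", "B", "A", "C"))
  expect_false(r$accepted)
  expect_equal(r$reason, "discordant_order")
})

test_that("concordance agrees with the periodicity oracle exhaustively", {
  for (len in 1:8) {
    grid <- as.matrix(expand.grid(rep(list(1:3), len)))
    for (row in seq_len(nrow(grid))) {
      labels <- unname(grid[row, ])
      expect_equal(check_concordance(labels)$accepted, bf_periodic(labels),
                   info = paste(labels, collapse = ","))
    }
  }
})

test_that("pass counting takes the minimum over fragments", {
  pc <- count_passes(c("A", "B", "A", "B", "A"), c("A", "B"))
  expect_equal(unname(pc$counts), c(3L, 2L))
  expect_equal(pc$full_passes, 2L)

  pc <- count_passes(c("A", "A"), "A")
  expect_equal(pc$full_passes, 2L)

  set.seed(5)
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    reps <- sample(1:6, 1)
    labels <- rep(letters[1:k], reps)
    extra <- sample(0:(k - 1), 1)
    labels <- c(labels, letters[seq_len(extra)])
    conc <- check_concordance(labels)
    expect_true(conc$accepted)
    pc <- count_passes(labels, conc$cycle)
    bf <- min(vapply(unique(labels), function(x) sum(labels == x), integer(1)))
    expect_equal(pc$full_passes, bf)
  }
})

test_that("boundary voting is the mode with median-then-smaller ties", {
  expect_equal(mode_vote(c(1000L, 1000L, 1012L)), 1000L)
  expect_equal(mode_vote(42L), 42L)
  expect_equal(mode_vote(c(5L, 7L)), 5L)          # tie of two: smaller
  expect_equal(mode_vote(c(5L, 7L, 9L)), 7L)      # tie of three: median

  set.seed(9)
  for (rep in 1:1000) {
    v <- sample(1:6, sample(1:9, 1), replace = TRUE)
    expect_equal(mode_vote(v), bf_mode(v))
  }

  b <- vote_boundaries(c(100L, 100L, 120L), c(300L, 310L, 310L))
  expect_equal(unname(b), c(100L, 310L))
})

test_that("threading is a fixed point when sub-reads abut exactly", {
  sr <- make_sr(rep(1000L, 3), rep(2000L, 3))
  frag <- data.frame(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
                     stringsAsFactors = FALSE)
  tr <- thread_refine(frag, rep(1L, 3), 1L, sr, caller_params())
  expect_true(tr$ok)
  expect_equal(tr$fragments$start, 1000L)
  expect_equal(tr$fragments$end, 2000L)
  expect_equal(tr$junctions$delta, 0)
})

test_that("threading recovers boundaries clipped in query space", {
  # every pass's alignment loses its last 7 query bases at the junction
  sr <- make_sr(rep(1000L, 3), rep(1993L, 3),
                qstart = c(0L, 1000L, 2000L), qend = c(993L, 1993L, 2993L))
  frag <- data.frame(chrom = "chr1", start = 1000L, end = 1993L, strand = "+",
                     stringsAsFactors = FALSE)
  tr <- thread_refine(frag, rep(1L, 3), 1L, sr, caller_params())
  expect_true(tr$ok)
  expect_equal(tr$fragments$end, 2000L)   # truth boundary restored
  expect_equal(tr$junctions$delta, 7)
  expect_true(tr$junctions$applied)

  # overlap in query space trims the boundary back
  sr <- make_sr(rep(1000L, 3), rep(2007L, 3),
                qstart = c(0L, 1000L, 2000L), qend = c(1007L, 2007L, 3007L))
  frag <- data.frame(chrom = "chr1", start = 1000L, end = 2007L, strand = "+",
                     stringsAsFactors = FALSE)
  tr <- thread_refine(frag, rep(1L, 3), 1L, sr, caller_params())
  expect_equal(tr$fragments$end, 2000L)

  # a gap beyond the tolerance is flagged, not applied
  sr <- make_sr(rep(1000L, 3), rep(1900L, 3),
                qstart = c(0L, 1000L, 2000L), qend = c(900L, 1900L, 2900L))
  frag <- data.frame(chrom = "chr1", start = 1000L, end = 1900L, strand = "+",
                     stringsAsFactors = FALSE)
  tr <- thread_refine(frag, rep(1L, 3), 1L, sr, caller_params())
  expect_true(tr$junctions$flagged)
  expect_equal(tr$fragments$end, 1900L)
})

test_that("after refinement the residual junction gap is zero on simulated reads", {
  sim <- simulate_rca(sim_params(seed = 21, n_circles = 40, jitter = 8,
                                 variant_rate = 0, extra_reads_lambda = 0,
                                 pass_probs = c("3" = 0.5, "4" = 0.5),
                                 mapq_probs = c("60" = 1)))
  calls <- call_circles(sim$paf)
  acc <- accepted_calls(calls)
  expect_gt(length(acc), 30L)
  for (cc in acc) {
    j <- cc$junctions
    expect_true(all(j$applied | is.na(j$delta) | j$delta == 0 | j$flagged))
  }
})

test_that("noise-free simulated circles are recovered exactly", {
  sim <- simulate_rca(zero_noise_params(seed = 4, n = 60))
  calls <- call_circles(sim$paf)
  acc <- accepted_calls(calls)
  expect_equal(length(acc), nrow(sim$reads))
  truth <- truth_by_id(sim)
  for (cc in acc) {
    cid <- sim$reads$circle_id[sim$reads$read_id == cc$read_id]
    expect_identical(canonicalize_circle(cc$fragments)$key,
                     canonicalize_circle(truth[[cid]]$fragments)$key)
  }
})

test_that("reads with fewer than the required full passes are rejected", {
  sim <- simulate_rca(zero_noise_params(seed = 6, n = 25))
  truth <- truth_by_id(sim)
  # one full cycle plus a half copy of the first fragment: 1 full pass
  recs <- list()
  for (r in seq_len(nrow(sim$reads))) {
    circ <- truth[[sim$reads$circle_id[r]]]
    f <- circ$fragments
    len <- f$end - f$start
    q <- cumsum(c(0L, len))
    rows <- data.frame(qname = sim$reads$read_id[r], qlen = sum(len) * 2L,
                       qstart = q[seq_len(nrow(f))], qend = q[-1L],
                       strand = f$strand, tname = f$chrom, tlen = 300000L,
                       tstart = f$start, tend = f$end, nmatch = len,
                       alnlen = len, mapq = 60L,
                       cs = paste0(":", len), tags = "",
                       stringsAsFactors = FALSE)
    half <- as.integer(floor(len[1L] / 2))
    part <- rows[1L, ]
    part$qstart <- q[nrow(f) + 1L]; part$qend <- part$qstart + half
    if (f$strand[1L] == "+") {
      part$tend <- part$tstart + half
    } else {
      part$tstart <- part$tend - half
    }
    part$nmatch <- half; part$alnlen <- half; part$cs <- paste0(":", half)
    recs[[r]] <- rbind(rows, part)
  }
  paf <- do.call(rbind, recs)
  calls <- call_circles(paf)
  df <- as.data.frame(calls)
  expect_equal(sum(df$status == "accepted"), 0L)
  expect_true(all(df$reason == "insufficient_passes"))
})

test_that("an opposite-strand sub-read at the same locus rejects the read", {
  sr <- make_sr(rep(1000L, 4), rep(1800L, 4), strand = c("+", "-", "+", "-"))
  sr$qname <- "flip"
  calls <- call_circles(sr[, setdiff(names(sr), "rank")])
  df <- as.data.frame(calls)
  expect_equal(df$status, "rejected")
  expect_equal(df$reason, "discordant_strand")
})

test_that("single-alignment reads are uncertain and rejected", {
  sr <- make_sr(1000L, 1800L)
  calls <- call_circles(sr[, setdiff(names(sr), "rank")])
  expect_equal(as.data.frame(calls)$reason, "single_hit")
})

test_that("calling is deterministic and acceptance is monotone in min passes", {
  sim <- simulate_rca(sim_params(seed = 8, n_circles = 40, jitter = 6,
                                 extra_reads_lambda = 0))
  c1 <- as.data.frame(call_circles(sim$paf))
  c2 <- as.data.frame(call_circles(sim$paf))
  expect_identical(c1, c2)

  strict <- as.data.frame(call_circles(sim$paf, caller_params(min_full_passes = 3)))
  loose <- as.data.frame(call_circles(sim$paf, caller_params(min_full_passes = 2)))
  acc_strict <- strict$read_id[strict$status == "accepted"]
  acc_loose <- loose$read_id[loose$status == "accepted"]
  expect_true(all(acc_strict %in% acc_loose))
})

test_that("raising max_offset never splits clusters of well-separated loci", {
  set.seed(15)
  for (rep in 1:50) {
    n_loci <- sample(1:3, 1)
    base_start <- sample(seq(1000L, 90000L, by = 3000L), n_loci)
    base_end <- base_start + 500L
    pick <- sample(n_loci, 8, replace = TRUE)
    start <- base_start[pick] + sample(-5:5, 8, replace = TRUE)
    end <- base_end[pick] + sample(-5:5, 8, replace = TRUE)
    sr <- make_sr(start, end)
    for (off in c(10L, 20L, 40L)) {
      lab_small <- cluster_loci(sr, caller_params(max_offset = off))$labels
      lab_big <- cluster_loci(sr, caller_params(max_offset = off + 20L))$labels
      same_small <- outer(lab_small, lab_small, "==")
      same_big <- outer(lab_big, lab_big, "==")
      expect_true(all(same_big[same_small]))
    }
  }
})

test_that("full passes times circle length equals the aligned query span at zero error", {
  sim <- simulate_rca(zero_noise_params(seed = 10, n = 30, random_phase = FALSE))
  calls <- call_circles(sim$paf)
  for (cc in accepted_calls(calls)) {
    expect_equal(cc$full_passes * cc$circle_length, cc$qspan)
  }
})
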