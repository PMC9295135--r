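# Brute-force oracles (independent of the package's code paths) and small
# fixture builders shared across the test files.

# mode with median-then-smaller tie-break, by naive counting
bf_mode <- function(v) {
  vals <- sort(unique(v))
  cnt <- vapply(vals, function(x) sum(v == x), integer(1))
  tied <- vals[cnt == max(cnt)]
  tied[ceiling(length(tied) / 2)]
}

# is a label sequence the periodic extension of its first-appearance cycle?
bf_periodic <- function(labels) {
  n <- length(labels)
  k <- length(unique(labels))
  if (anyDuplicated(labels[seq_len(k)])) return(FALSE)
  i <- seq_len(max(0L, n - k))
  all(labels[i + k] == labels[i])
}

# greedy representative clustering, written naively over a plain matrix
bf_cluster <- function(chrom, strand, start, end, off) {
  labels <- integer(length(start))
  rep_chrom <- character(0); rep_strand <- character(0)
  rep_start <- integer(0); rep_end <- integer(0)
  for (i in seq_along(start)) {
    assigned <- 0L
    j <- 1L
    while (j <= length(rep_start) && assigned == 0L) {
      if (chrom[i] == rep_chrom[j] && strand[i] == rep_strand[j] &&
          abs(start[i] - rep_start[j]) <= off && abs(end[i] - rep_end[j]) <= off) {
        assigned <- j
      }
      j <- j + 1L
    }
    if (assigned == 0L) {
      rep_chrom <- c(rep_chrom, chrom[i]); rep_strand <- c(rep_strand, strand[i])
      rep_start <- c(rep_start, start[i]); rep_end <- c(rep_end, end[i])
      assigned <- length(rep_start)
    }
    labels[i] <- assigned
  }
  labels
}

# sub-read data.frame builder (one read, already in rank order)
make_sr <- function(tstart, tend, chrom = "chr1", strand = "+",
                    qstart = NULL, qend = NULL, mapq = 60L,
                    qname = "read1", cs = NA_character_, qlen = NULL) {
  n <- length(tstart)
  len <- tend - tstart
  if (is.null(qstart)) qstart <- cumsum(c(0L, len))[seq_len(n)]
  if (is.null(qend)) qend <- qstart + len
  if (is.null(qlen)) qlen <- max(qend)
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = rep_len(strand, n), tname = rep_len(chrom, n),
             tlen = 1000000L, tstart = tstart, tend = tend,
             nmatch = len, alnlen = len, mapq = rep_len(as.integer(mapq), n),
             cs = rep_len(cs, n), tags = "", rank = seq_len(n),
             stringsAsFactors = FALSE)
}

# random valid PAF record table for round-trip fuzzing
random_paf_records <- function(n) {
  qlen <- sample(500:5000, n, replace = TRUE)
  qstart <- vapply(qlen, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
  qend <- vapply(seq_len(n), function(i) {
    qstart[i] + sample.int(qlen[i] - qstart[i], 1L)
  }, integer(1))
  tlen <- sample(10000:100000, n, replace = TRUE)
  span <- qend - qstart
  tstart <- vapply(seq_len(n), function(i) {
    sample.int(tlen[i] - span[i], 1L) - 1L
  }, integer(1))
  alnlen <- span
  cs <- ifelse(stats::runif(n) < 0.5, paste0(":", span), NA_character_)
  tags <- ifelse(stats::runif(n) < 0.5,
                 sprintf("tp:A:P\tNM:i:%d", sample(0:9, n, replace = TRUE)), "")
  data.frame(qname = sprintf("q%04d", sample.int(9999L, n)), qlen = qlen,
             qstart = qstart, qend = qend,
             strand = sample(c("+", "-"), n, replace = TRUE),
             tname = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
             tlen = tlen, tstart = tstart, tend = tstart + span,
             nmatch = pmax(0L, span - sample(0:5, n, replace = TRUE)),
             alnlen = alnlen, mapq = sample(0:60, n, replace = TRUE),
             cs = cs, tags = tags, stringsAsFactors = FALSE)
}

# simulator presets for noise-free runs
zero_noise_params <- function(seed = 1L, n = 50L,
                              pass_probs = c("3" = 0.4, "4" = 0.3, "5" = 0.3),
                              ...) {
  sim_params(seed = seed, n_circles = n, jitter = 0L, variant_rate = 0,
             sub_rate = 0, ins_rate = 0, del_rate = 0,
             extra_reads_lambda = 0, pass_probs = pass_probs,
             mapq_probs = c("60" = 1), ...)
}

truth_by_id <- function(sim) {
  stats::setNames(sim$circles, vapply(sim$circles, `[[`, character(1), "id"))
}

# does every truth fragment have a matching call fragment within tol bp?
call_matches_truth <- function(call_frags, truth_frags, tol) {
  if (nrow(call_frags) != nrow(truth_frags)) return(FALSE)
  used <- rep(FALSE, nrow(call_frags))
  for (i in seq_len(nrow(truth_frags))) {
    hit <- which(!used &
                   call_frags$chrom == truth_frags$chrom[i] &
                   call_frags$strand == truth_frags$strand[i] &
                   abs(call_frags$start - truth_frags$start[i]) <= tol &
                   abs(call_frags$end - truth_frags$end[i]) <= tol)
    if (!length(hit)) return(FALSE)
    used[hit[1L]] <- TRUE
  }
  TRUE
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# rotation/orientation-insensitive sequence identity for circular molecules
circular_identical <- function(seq, template) {
  if (nchar(seq) != nchar(template)) return(FALSE)
  doubled <- paste0(template, template)
  grepl(seq, doubled, fixed = TRUE) || grepl(seq, revcomp_chr(doubled), fixed = TRUE)
}

rbind_frag_tables <- function(circles) {
  do.call(rbind, lapply(circles, `[[`, "fragments"))
}
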