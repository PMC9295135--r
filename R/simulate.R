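DNA_BASES <- c("A", "C", "G", "T")

# sample() expands a length-1 numeric x to 1:x; guard against that
draw_one <- function(values, prob) {
  if (length(values) == 1L) values else sample(values, 1L, prob = prob)
}

#' Simulation parameters for RCA concatemer reads
#'
#' Defaults emulate the study conditions of an apoptotic mESC eccDNA
#' library: circle sizes on a 188 bp nucleosomal lattice (multiplicity
#' distribution chosen so the median circle is about 1 kb, Gaussian
#' dispersion 15 bp), 1-7 genomic fragments per circle skewed heavily to
#' single-fragment circles, an X chromosome sampled at half the autosomal
#' rate (one X vs two autosomal copies in a diploid male genome), and most
#' circles captured by a single long read.
#'
#' @param seed integer RNG seed; every stage derives its stream from it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp); a
#'   chromosome named `chrX`/`X` is treated as the X.
#' @param gc reference GC fraction.
#' @param n_circles number of distinct circles to simulate.
#' @param k_probs named probabilities of fragment counts per circle.
#' @param period size-lattice period in bp (nucleosomal unit).
#' @param m_probs probabilities of lattice multiplicities 1..length(m_probs).
#' @param sigma Gaussian dispersion of circle length around the lattice (bp).
#' @param min_frag minimum fragment length (bp).
#' @param strand_prob probability a fragment joins in '+' orientation.
#' @param pass_probs named probabilities of template repetitions per read.
#' @param sub_rate,ins_rate,del_rate iid per-base error rates for the
#'   FASTQ read path (the direct-PAF path is error-free apart from injected
#'   variants and jitter).
#' @param jitter J: each reported alignment boundary moves by an independent
#'   uniform -J..+J bp in direct-PAF emission (clamped so intervals stay
#'   valid and on the chromosome/read).
#' @param mapq_probs named probabilities of mapping-quality values.
#' @param x_rate X-chromosome sampling-rate multiplier.
#' @param variant_rate per-base probability of an injected template SNV
#'   (placed at least 25 bp from fragment ends when the fragment allows).
#' @param extra_reads_lambda Poisson mean of additional reads per circle
#'   beyond the first (0.117 makes ~89% of circles single-read).
#' @param random_phase start each read at a random position of the circle;
#'   `FALSE` starts at the first fragment boundary (whole passes, exact
#'   length conservation).
#' @param min_seg partial flanking alignment segments shorter than this are
#'   not emitted (a real aligner does not report tiny terminal fragments).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 300000L, chr2 = 300000L,
                                         chr3 = 300000L, chrX = 300000L),
                       gc = 0.5,
                       n_circles = 200L,
                       k_probs = c("1" = 0.8, "2" = 0.15, "3" = 0.05),
                       period = 188,
                       m_probs = c(0.06, 0.08, 0.10, 0.12, 0.14, 0.16, 0.17, 0.17),
                       sigma = 15,
                       min_frag = 50L,
                       strand_prob = 0.5,
                       pass_probs = c("1" = 0.35, "2" = 0.25, "3" = 0.20,
                                      "4" = 0.12, "5" = 0.08),
                       sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.02,
                       jitter = 5L,
                       mapq_probs = c("60" = 0.90, "50" = 0.05,
                                      "40" = 0.03, "20" = 0.02),
                       x_rate = 0.5,
                       variant_rate = 0,
                       extra_reads_lambda = 0.117,
                       random_phase = TRUE,
                       min_seg = 30L) {
  if (is.null(names(m_probs))) names(m_probs) <- seq_along(m_probs)
  p <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths, gc = gc,
            n_circles = as.integer(n_circles), k_probs = k_probs,
            period = period, m_probs = m_probs, sigma = sigma,
            min_frag = as.integer(min_frag), strand_prob = strand_prob,
            pass_probs = pass_probs, sub_rate = sub_rate,
            ins_rate = ins_rate, del_rate = del_rate,
            jitter = as.integer(jitter), mapq_probs = mapq_probs,
            x_rate = x_rate, variant_rate = variant_rate,
            extra_reads_lambda = extra_reads_lambda,
            random_phase = isTRUE(random_phase), min_seg = as.integer(min_seg))
  stopifnot(all(p$chrom_lengths > 0), p$gc >= 0, p$gc <= 1,
            all(p$k_probs >= 0), all(p$m_probs >= 0), p$sigma >= 0,
            p$jitter >= 0, all(c(p$sub_rate, p$ins_rate, p$del_rate) >= 0),
            all(c(p$sub_rate, p$ins_rate, p$del_rate) <= 1))
  class(p) <- "sim_params"
  p
}

#' Generate a random reference genome
#'
#' @param params [sim_params()].
#' @return list with `ref` (a [Biostrings::DNAStringSet]) and `sizes`
#'   (data.frame `chrom`, `length`).
#' @export
generate_reference <- function(params) {
  set.seed(params$seed)
  prob <- c((1 - params$gc) / 2, params$gc / 2, params$gc / 2, (1 - params$gc) / 2)
  seqs <- vapply(params$chrom_lengths, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(params$chrom_lengths)
  list(ref = ref,
       sizes = data.frame(chrom = names(params$chrom_lengths),
                          length = as.integer(params$chrom_lengths),
                          stringsAsFactors = FALSE))
}

is_x_chrom <- function(chrom) chrom %in% c("chrX", "X")

#' Sample ground-truth circles
#'
#' Each circle draws a fragment count k, a total length on the size lattice
#' (`period * m + Normal(0, sigma)`, floored at `k * min_frag`), partitions
#' the length over fragments (each at least `min_frag`), and places each
#' fragment uniformly on a chromosome chosen with probability proportional
#' to length times the X-rate multiplier, with a random strand.
#'
#' @param params [sim_params()].
#' @param reference output of [generate_reference()] (used for variant
#'   reference bases; may be `NULL` when `variant_rate == 0`).
#' @return list of circle truth entries (`id`, `fragments`, `variants`,
#'   `length`).
#' @export
sample_circles <- function(params, reference = NULL) {
  set.seed(params$seed + 1L)
  chroms <- names(params$chrom_lengths)
  w <- as.numeric(params$chrom_lengths) *
    ifelse(is_x_chrom(chroms), params$x_rate, 1)
  ks <- as.integer(names(params$k_probs))
  ms <- as.integer(names(params$m_probs))
  circles <- vector("list", params$n_circles)
  for (i in seq_len(params$n_circles)) {
    k <- draw_one(ks, params$k_probs)
    m <- draw_one(ms, params$m_probs)
    total <- max(as.integer(round(params$period * m + stats::rnorm(1, 0, params$sigma))),
                 k * params$min_frag)
    parts <- params$min_frag +
      stats::rmultinom(1L, total - k * params$min_frag, rep(1, k))[, 1L]
    frag <- data.frame(chrom = character(k), start = integer(k),
                       end = integer(k), strand = character(k),
                       stringsAsFactors = FALSE)
    for (f in seq_len(k)) {
      for (try in 1:50) {
        ch <- draw_one(chroms, w)
        room <- params$chrom_lengths[[ch]] - parts[f]
        if (room >= 0) break
        if (try == 50L) stop("fragment cannot fit on any chromosome")
      }
      start <- sample.int(room + 1L, 1L) - 1L
      frag$chrom[f] <- ch
      frag$start[f] <- start
      frag$end[f] <- start + parts[f]
      frag$strand[f] <- if (stats::runif(1) < params$strand_prob) "+" else "-"
    }
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           frag = integer(), stringsAsFactors = FALSE)
    if (params$variant_rate > 0 && !is.null(reference)) {
      for (f in seq_len(k)) {
        len <- parts[f]
        pad <- if (len > 60L) 25L else 0L
        eligible <- seq.int(pad, len - 1L - pad)
        nv <- stats::rbinom(1L, len, params$variant_rate)
        nv <- min(nv, length(eligible))
        if (nv > 0L) {
          offs <- sort(sample(eligible, nv))
          pos <- frag$start[f] + offs
          rb <- strsplit(as.character(Biostrings::subseq(
            reference$ref[[frag$chrom[f]]], frag$start[f] + 1L, frag$end[f])), "")[[1L]][offs + 1L]
          ab <- vapply(rb, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
          variants <- rbind(variants,
                            data.frame(chrom = frag$chrom[f], pos = pos,
                                       ref = rb, alt = unname(ab), frag = f,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    circles[[i]] <- list(id = sprintf("circle_%05d", i), fragments = frag,
                         variants = variants, length = as.integer(total))
  }
  circles
}

#' Plus-strand-variant-aware circle template sequence
#'
#' @param circle a circle truth entry.
#' @param reference output of [generate_reference()] or a
#'   [Biostrings::DNAStringSet].
#' @return the circular template as a character string (traversal starting
#'   at fragment 1).
#' @export
circle_template <- function(circle, reference) {
  ref <- if (is.list(reference) && !is.null(reference$ref)) reference$ref else reference
  pieces <- character(nrow(circle$fragments))
  for (f in seq_len(nrow(circle$fragments))) {
    fr <- circle$fragments[f, ]
    s <- as.character(Biostrings::subseq(ref[[fr$chrom]], fr$start + 1L, fr$end))
    v <- circle$variants[circle$variants$frag == f, , drop = FALSE]
    if (nrow(v)) {
      ch <- strsplit(s, "")[[1L]]
      ch[v$pos - fr$start + 1L] <- v$alt
      s <- paste(ch, collapse = "")
    }
    if (fr$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    pieces[f] <- s
  }
  paste(pieces, collapse = "")
}

#' Sample reads for the simulated circles
#'
#' Each circle is covered by `1 + Poisson(extra_reads_lambda)` reads; each
#' read has its own random phase and repetition count.
#'
#' @param params [sim_params()].
#' @param circles output of [sample_circles()].
#' @return data.frame: `read_id`, `circle_id`, `phase`, `passes`,
#'   `read_length`.
#' @export
sample_reads <- function(params, circles) {
  set.seed(params$seed + 2L)
  passes_vals <- as.integer(names(params$pass_probs))
  rows <- list()
  idx <- 0L
  for (circle in circles) {
    n_reads <- 1L + stats::rpois(1L, params$extra_reads_lambda)
    for (r in seq_len(n_reads)) {
      idx <- idx + 1L
      phase <- if (params$random_phase) sample.int(circle$length, 1L) - 1L else 0L
      passes <- draw_one(passes_vals, params$pass_probs)
      rows[[idx]] <- data.frame(read_id = sprintf("read_%06d", idx),
                                circle_id = circle$id, phase = phase,
                                passes = passes,
                                read_length = passes * circle$length,
                                stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(), circle_id = character(),
                      phase = integer(), passes = integer(),
                      read_length = integer(), stringsAsFactors = FALSE)
  }
  out
}

# Decompose one read (phase + repetitions of the circle) into maximal
# alignment segments; each segment lies within one fragment.
read_segments <- function(circle, phase, passes) {
  lens <- circle$fragments$end - circle$fragments$start
  L <- sum(lens)
  b <- cumsum(c(0L, lens))
  total <- passes * L
  segs <- list()
  cur <- phase %% L
  q <- 0L
  while (q < total) {
    j <- findInterval(cur, b)
    len <- min(b[j + 1L] - cur, total - q)
    segs[[length(segs) + 1L]] <- list(frag = j, local = cur - b[j],
                                      len = len, qstart = q,
                                      full = (len == lens[j]))
    q <- q + len
    cur <- cur + len
    if (cur >= L) cur <- 0L
  }
  segs
}

cs_for_interval <- function(variants, ts, te) {
  v <- variants[variants$pos >= ts & variants$pos < te, , drop = FALSE]
  if (!nrow(v)) return(list(cs = paste0(":", te - ts), n_sub = 0L))
  v <- v[order(v$pos), , drop = FALSE]
  ops <- character(0)
  cur <- ts
  for (i in seq_len(nrow(v))) {
    if (v$pos[i] > cur) ops <- c(ops, paste0(":", v$pos[i] - cur))
    ops <- c(ops, paste0("*", tolower(v$ref[i]), tolower(v$alt[i])))
    cur <- v$pos[i] + 1L
  }
  if (te > cur) ops <- c(ops, paste0(":", te - cur))
  list(cs = paste(ops, collapse = ""), n_sub = nrow(v))
}

#' Emit direct PAF records for simulated reads
#'
#' Bypasses the external aligner: each read is decomposed into its true
#' alignment segments (one per pass per fragment, plus partial flanks from
#' the random phase), each segment's target interval is clipped by
#' independent uniform jitter up to J at both ends, mapping qualities are
#' drawn from the configured distribution, and a short-form cs tag
#' consistent with the injected variants and the clipped interval is
#' attached.
#'
#' @param params [sim_params()].
#' @param circles output of [sample_circles()].
#' @param reads output of [sample_reads()].
#' @return PAF data.frame (same shape as [parse_paf()] output).
#' @export
emit_direct_paf <- function(params, circles, reads) {
  set.seed(params$seed + 3L)
  by_id <- stats::setNames(circles, vapply(circles, `[[`, character(1), "id"))
  mq_vals <- as.integer(names(params$mapq_probs))
  J <- params$jitter
  recs <- list()
  for (r in seq_len(nrow(reads))) {
    circle <- by_id[[reads$circle_id[r]]]
    lens <- circle$fragments$end - circle$fragments$start
    segs <- read_segments(circle, reads$phase[r], reads$passes[r])
    qlen <- reads$read_length[r]
    for (sg in segs) {
      fr <- circle$fragments[sg$frag, ]
      if (fr$strand == "+") {
        ts <- fr$start + sg$local
      } else {
        ts <- fr$end - sg$local - sg$len
      }
      te <- ts + sg$len
      if (!sg$full && sg$len < params$min_seg) next
      # symmetric boundary jitter: each end moves by uniform -J..J
      # (negative shrinks, positive extends the reported alignment)
      u1 <- if (J > 0L) sample.int(2L * J + 1L, 1L) - J - 1L else 0L
      u2 <- if (J > 0L) sample.int(2L * J + 1L, 1L) - J - 1L else 0L
      tlen <- as.integer(params$chrom_lengths[[fr$chrom]])
      qs0 <- sg$qstart; qe0 <- sg$qstart + sg$len
      # u1 acts on the target start, u2 on the target end; on the query the
      # target-start side is the read-left end for '+' and read-right for '-'
      u1 <- max(u1, -(sg$len - 1L))          # keep interval non-empty
      u2 <- max(u2, -(sg$len - 1L) - min(u1, 0L))
      u1 <- min(u1, ts)                      # stay on the chromosome
      u2 <- min(u2, tlen - te)
      if (fr$strand == "+") {
        u1 <- min(u1, qs0)                   # stay within the read
        u2 <- min(u2, qlen - qe0)
        qs <- qs0 - u1; qe <- qe0 + u2
      } else {
        u2 <- min(u2, qs0)
        u1 <- min(u1, qlen - qe0)
        qs <- qs0 - u2; qe <- qe0 + u1
      }
      tsc <- ts - u1
      tec <- te + u2
      cs <- cs_for_interval(circle$variants, tsc, tec)
      mapq <- draw_one(mq_vals, params$mapq_probs)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = reads$read_id[r], qlen = qlen, qstart = qs, qend = qe,
        strand = fr$strand, tname = fr$chrom,
        tlen = as.integer(params$chrom_lengths[[fr$chrom]]),
        tstart = tsc, tend = tec,
        nmatch = (tec - tsc) - cs$n_sub, alnlen = tec - tsc,
        mapq = mapq, cs = cs$cs, tags = "tp:A:P",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty_paf())
  rbind_rows(recs)
}

#' Simulate one read sequence with Nanopore-like errors
#'
#' The read is the circle template rotated to the read's phase, repeated
#' `passes` times, then passed through an iid per-base error process
#' (substitution, insertion after the base, deletion).
#'
#' @param circle circle truth entry.
#' @param reference reference genome.
#' @param phase 0-based start offset within the circle.
#' @param passes number of template repetitions.
#' @param params [sim_params()].
#' @return read sequence as a character string.
#' @export
simulate_read <- function(circle, reference, phase, passes,
                          params = sim_params()) {
  template <- circle_template(circle, reference)
  L <- nchar(template)
  rot <- if (phase %% L > 0L) {
    p <- phase %% L
    paste0(substr(template, p + 1L, L), substr(template, 1L, p))
  } else template
  read <- strrep(rot, passes)
  apply_errors(read, params$sub_rate, params$ins_rate, params$del_rate)
}

apply_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (sub_rate > 0) {
    m <- which(stats::runif(n) < sub_rate)
    if (length(m)) {
      ch[m] <- vapply(ch[m], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
    }
  }
  del <- if (del_rate > 0) stats::runif(n) < del_rate else logical(n)
  ins <- if (ins_rate > 0) stats::runif(n) < ins_rate else logical(n)
  ch[del] <- ""
  w <- which(ins & !del)
  if (length(w)) ch[w] <- paste0(ch[w], sample(DNA_BASES, length(w), replace = TRUE))
  w2 <- which(ins & del)
  if (length(w2)) ch[w2] <- sample(DNA_BASES, length(w2), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate read sequences for all simulated reads
#'
#' @param params [sim_params()].
#' @param circles,reads simulation truth.
#' @param reference reference genome.
#' @return named character vector of read sequences.
#' @export
sim_read_sequences <- function(params, circles, reads, reference) {
  set.seed(params$seed + 4L)
  by_id <- stats::setNames(circles, vapply(circles, `[[`, character(1), "id"))
  seqs <- character(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    seqs[r] <- simulate_read(by_id[[reads$circle_id[r]]], reference,
                             reads$phase[r], reads$passes[r], params)
  }
  stats::setNames(seqs, reads$read_id)
}

#' Run the full simulation
#'
#' @param params [sim_params()].
#' @param sequences also generate error-bearing read sequences (FASTQ path).
#' @return list of class `rca_sim`: `params`, `reference`, `circles`,
#'   `reads`, `paf`, and optionally `seqs`.
#' @export
simulate_rca <- function(params = sim_params(), sequences = FALSE) {
  reference <- generate_reference(params)
  circles <- sample_circles(params, reference)
  reads <- sample_reads(params, circles)
  paf <- emit_direct_paf(params, circles, reads)
  out <- list(params = params, reference = reference, circles = circles,
              reads = reads, paf = paf)
  if (sequences) out$seqs <- sim_read_sequences(params, circles, reads, reference)
  structure(out, class = "rca_sim")
}

truth_circle_table <- function(circles) {
  empty <- data.frame(circle_id = character(), length = integer(),
                      n_fragments = integer(), fragments = character(),
                      n_variants = integer(), stringsAsFactors = FALSE)
  if (!length(circles)) return(empty)
  rbind_rows(lapply(circles, function(circle) {
    data.frame(circle_id = circle$id, length = circle$length,
               n_fragments = nrow(circle$fragments),
               fragments = fragments_string(circle$fragments),
               n_variants = nrow(circle$variants),
               stringsAsFactors = FALSE)
  }))
}

#' Write all simulation artifacts
#'
#' Emits the reference FASTA and chrom.sizes, the direct-PAF alignments,
#' FASTQ reads when sequences were generated, ground-truth TSVs and a JSON
#' manifest with the parameters and seed. All files round-trip through the
#' package's own readers.
#'
#' @param sim output of [simulate_rca()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             sizes = file.path(dir, "chrom.sizes"),
             paf = file.path(dir, "alignments.paf"),
             circles = file.path(dir, "truth_circles.tsv"),
             reads = file.path(dir, "truth_reads.tsv"),
             manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(sim$reference$ref, paths[["reference"]])
  utils::write.table(sim$reference$sizes, paths[["sizes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_paf(sim$paf, paths[["paf"]])
  utils::write.table(truth_circle_table(sim$circles), paths[["circles"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$reads, paths[["reads"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- sim$params
  class(manifest) <- NULL
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(sim$seqs)) {
    paths <- c(paths, fastq = file.path(dir, "reads.fastq"))
    fq <- character(4L * length(sim$seqs))
    fq[seq(1L, length(fq), 4L)] <- paste0("@", names(sim$seqs))
    fq[seq(2L, length(fq), 4L)] <- sim$seqs
    fq[seq(3L, length(fq), 4L)] <- "+"
    fq[seq(4L, length(fq), 4L)] <- strrep("I", nchar(sim$seqs))
    writeLines(fq, paths[["fastq"]])
  }
  invisible(paths)
}
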