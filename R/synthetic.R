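# Seeded synthetic-data generators with recorded ground truth: genome +
# annotation with planted motif instances, strand-specific methylome, and
# thermogram sets.  Background sequence is i.i.d. (the census logic is
# position-exact, not composition-sensitive); spurious background motif
# matches are permitted and accounted for by the naive reference scanner.

#' Generate a synthetic genome with planted motif instances
#'
#' Draws i.i.d. background sequence at a given GC content, lays out genes
#' with room for a full upstream promoter window, and overwrites planted
#' occurrences of the degenerate pattern (degenerate positions sampled
#' uniformly from their allowed base sets) at recorded loci inside promoter
#' windows, on random strands.  Planted sequences are validated against the
#' pattern at write time.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param n_genes Total number of genes.
#' @param n_planted Total number of planted motif instances.
#' @param gc GC fraction of the background.
#' @param pattern IUPAC pattern to plant (default `"AACNDN"`).
#' @param upstream_length Promoter window length (bp).
#' @param seed RNG seed (local to this call).
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3` and `truth.json`.
#' @return List of class `"synthetic_genome"`: `$genome`
#'   ([Biostrings::DNAStringSet]), `$annotation`, `$truth` (list with
#'   `$planted` table, parameters, seed), and `$paths` when written.
#' @export
gen_genome <- function(n_chrom = 1L, chrom_len = 100000L, n_genes = 20L,
                       n_planted = 50L, gc = 0.36, pattern = "AACNDN",
                       upstream_length = 3000L, seed = 1L, out_dir = NULL) {
  pattern <- motif_pattern(pattern)
  plen <- nchar(pattern)
  margin <- upstream_length + 500L
  if (chrom_len < 2L * margin + 1000L)
    stop("chrom_len too short for upstream_length; need > ",
         2L * margin + 1000L)
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    pA <- (1 - gc) / 2
    probs <- c(A = pA, C = gc / 2, G = gc / 2, T = pA)
    seqs <- lapply(chroms, function(ch)
      sample(names(probs), chrom_len, replace = TRUE, prob = probs))
    names(seqs) <- chroms

    # gene layout: TSS positions evenly spaced inside [margin, len - margin]
    genes_per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1L)))
    ann <- list()
    g <- 0L
    for (ci in seq_len(n_chrom)) {
      ng <- genes_per[ci]
      if (!ng) next
      tss <- round(seq(margin, chrom_len - margin, length.out = ng))
      glen <- sample(500:1500, ng, replace = TRUE)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      for (k in seq_len(ng)) {
        g <- g + 1L
        if (strand[k] == "+") {
          gs <- tss[k]; ge <- min(tss[k] + glen[k], chrom_len)
        } else {
          ge <- tss[k]; gs <- max(tss[k] - glen[k], 0L)
        }
        ann[[g]] <- data.frame(
          gene_id = sprintf("g%04d", g), chrom = chroms[ci],
          start = gs, end = ge, strand = strand[k],
          stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, ann)
    promoters <- derive_promoters(
      ann, setNames(rep(chrom_len, n_chrom), chroms), upstream_length)

    # plant motifs inside promoter windows, non-overlapping
    occupied <- lapply(chroms, function(ch) logical(chrom_len))
    names(occupied) <- chroms
    sym_sets <- IUPAC_SETS[strsplit(unclass(pattern), "")[[1L]]]
    planted <- list()
    tries <- 0L
    while (length(planted) < n_planted && tries < 50L * n_planted) {
      tries <- tries + 1L
      w <- promoters[sample.int(nrow(promoters), 1L), ]
      if (w$end - w$start < plen) next
      s0 <- w$start + sample.int(w$end - w$start - plen + 1L, 1L) - 1L
      span <- (s0 + 1L):(s0 + plen)
      if (any(occupied[[w$chrom]][span])) next
      occupied[[w$chrom]][span] <- TRUE
      strand <- sample(c("+", "-"), 1L)
      mseq <- paste(vapply(sym_sets, function(s)
        if (length(s) == 1L) s else sample(s, 1L), character(1L)),
        collapse = "")
      stopifnot(matches_pattern(mseq, pattern))  # validate at write time
      write_seq <- if (strand == "+") mseq else revcomp_chr(mseq)
      seqs[[w$chrom]][span] <- strsplit(write_seq, "")[[1L]]
      planted[[length(planted) + 1L]] <- data.frame(
        chrom = w$chrom, start = s0, end = s0 + plen, strand = strand,
        seq = mseq, gene_id = w$gene_id, stringsAsFactors = FALSE)
    }
    if (length(planted) < n_planted)
      warning("placed only ", length(planted), " of ", n_planted,
              " requested motifs")
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), seq = character(),
                 gene_id = character(), stringsAsFactors = FALSE)
    planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
    rownames(planted) <- NULL

    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1L), collapse = ""))
    names(genome) <- chroms
    truth <- list(planted = planted, pattern = unclass(pattern),
                  upstream_length = upstream_length, gc = gc, seed = seed,
                  n_chrom = n_chrom, chrom_len = chrom_len)
    out <- list(genome = genome, annotation = ann, promoters = promoters,
                truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(out_dir, "genome.fa")
      gff <- file.path(out_dir, "genes.gff3")
      tj <- file.path(out_dir, "truth.json")
      Biostrings::writeXStringSet(genome, fa)
      writeLines(c("##gff-version 3",
                   sprintf("%s\tmybdna\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                           ann$chrom, ann$start + 1L, ann$end, ann$strand,
                           ann$gene_id)), gff)
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      out$paths <- list(genome = fa, annotation = gff, truth = tj)
    }
    class(out) <- "synthetic_genome"
    out
  })
}

#' Generate a synthetic methylome over planted motifs
#'
#' Draws independent methylation flags for each planted motif (5mC at the
#' position-3 cytosine, 6mA at the position-1 and position-2 adenines of the
#' AAC core, all on the motif strand) and sprinkles background calls at rate
#' `p_background` per chemically valid base (C for 5mC, A for 6mA, either
#' strand).  Default rates echo the strongly skewed abundance seen in plant
#' methylomes (5mC much more common than 6mA, position 2 more often modified
#' than position 1).
#'
#' @param synth A `"synthetic_genome"` from [gen_genome()].
#' @param p_5mC_pos3,p_6mA_pos1,p_6mA_pos2 Per-motif flag probabilities.
#' @param p_background Per-base background call rate.
#' @param seed RNG seed (local).
#' @param out_dir Optional directory; writes `m5C.bed`, `m6A.bed`,
#'   `methylome_truth.json`.
#' @return List of class `"synthetic_methylome"`: `$calls` (all calls,
#'   [load_methylation()] layout), `$flags` (per planted motif), `$paths`
#'   when written.
#' @export
gen_methylome <- function(synth, p_5mC_pos3 = 0.10, p_6mA_pos1 = 0.005,
                          p_6mA_pos2 = 0.015, p_background = 0.001,
                          seed = 1L, out_dir = NULL) {
  stopifnot(inherits(synth, "synthetic_genome"))
  p <- c(p_5mC_pos3, p_6mA_pos1, p_6mA_pos2, p_background)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  planted <- synth$truth$planted
  with_seed(seed, {
    nf <- nrow(planted)
    flags <- data.frame(
      planted[c("chrom", "start", "end", "strand")],
      m5c_pos3 = runif(nf) < p_5mC_pos3,
      m6a_pos1 = runif(nf) < p_6mA_pos1,
      m6a_pos2 = runif(nf) < p_6mA_pos2)
    call_rows <- list()
    add_calls <- function(chrom, pos, strand, type) {
      if (!length(pos)) return()
      call_rows[[length(call_rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = as.integer(pos), strand = strand,
        mod_type = type, score = 1, stringsAsFactors = FALSE)
    }
    coord <- function(k) motif_position_coord(planted$start, planted$end,
                                              planted$strand, k)
    i5 <- which(flags$m5c_pos3)
    add_calls(planted$chrom[i5], coord(3L)[i5], planted$strand[i5], "5mC")
    i1 <- which(flags$m6a_pos1)
    add_calls(planted$chrom[i1], coord(1L)[i1], planted$strand[i1], "6mA")
    i2 <- which(flags$m6a_pos2)
    add_calls(planted$chrom[i2], coord(2L)[i2], planted$strand[i2], "6mA")
    if (p_background > 0) {
      for (ch in names(synth$genome)) {
        b <- strsplit(as.character(synth$genome[[ch]]), "")[[1L]]
        for (spec in list(list(base = "C", strand = "+", type = "5mC"),
                          list(base = "G", strand = "-", type = "5mC"),
                          list(base = "A", strand = "+", type = "6mA"),
                          list(base = "T", strand = "-", type = "6mA"))) {
          cand <- which(b == spec$base) - 1L
          keep <- cand[runif(length(cand)) < p_background]
          add_calls(ch, keep, spec$strand, spec$type)
        }
      }
    }
    calls <- if (length(call_rows)) do.call(rbind, call_rows) else
      data.frame(chrom = character(), pos = integer(), strand = character(),
                 mod_type = character(), score = numeric(),
                 stringsAsFactors = FALSE)
    calls <- calls[!duplicated(calls[c("chrom", "pos", "strand", "mod_type")]),
                   , drop = FALSE]
    calls <- calls[order(calls$chrom, calls$pos, calls$strand), , drop = FALSE]
    rownames(calls) <- NULL
    out <- list(calls = calls, flags = flags,
                rates = list(p_5mC_pos3 = p_5mC_pos3, p_6mA_pos1 = p_6mA_pos1,
                             p_6mA_pos2 = p_6mA_pos2,
                             p_background = p_background, seed = seed))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bed <- function(df, path) {
        write.table(data.frame(df$chrom, df$pos, df$pos + 1L, ".", df$score,
                               df$strand),
                    path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        path
      }
      p5 <- write_bed(calls[calls$mod_type == "5mC", ],
                      file.path(out_dir, "m5C.bed"))
      p6 <- write_bed(calls[calls$mod_type == "6mA", ],
                      file.path(out_dir, "m6A.bed"))
      tj <- file.path(out_dir, "methylome_truth.json")
      jsonlite::write_json(out[c("flags", "rates")], tj, auto_unbox = TRUE,
                           digits = NA)
      out$paths <- list(m5C = p5, m6A = p6, truth = tj)
    }
    class(out) <- "synthetic_methylome"
    out
  })
}

#' Naive reference census
#'
#' Computes the motif-methylation census entirely through the naive
#' string-based scanner and direct coordinate lookups, independently of
#' [scan_motifs()]/[attach_methylation()].  Used to score the production
#' pipeline against synthetic ground truth even in the presence of background
#' motif matches and background methylation calls.
#'
#' @param seqs Named character vector of chromosome sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param calls Methylation call table ([load_methylation()] layout).
#' @param promoters Promoter window table.
#' @param pattern IUPAC pattern string.
#' @return A `"motif_census"` (see [tally_census()]).
#' @export
census_naive <- function(seqs, calls, promoters, pattern = "AACNDN") {
  if (methods::is(seqs, "DNAStringSet"))
    seqs <- setNames(as.character(seqs), names(seqs))
  inst <- scan_motifs_naive(seqs, pattern, windows = promoters)
  key <- function(chrom, pos, strand, type)
    paste(chrom, pos, strand, type, sep = ":")
  callset <- if (is.null(calls) || !nrow(calls)) character() else
    key(calls$chrom, calls$pos, calls$strand, calls$mod_type)
  flag <- function(i, k, type) {
    pos <- if (inst$strand[i] == "+") inst$start[i] + k - 1L else
      inst$end[i] - k
    key(inst$chrom[i], pos, inst$strand[i], type) %in% callset
  }
  n <- nrow(inst)
  m5 <- logical(n); a1 <- logical(n); a2 <- logical(n)
  for (i in seq_len(n)) {
    m5[i] <- flag(i, 3L, "5mC")
    a1[i] <- flag(i, 1L, "6mA")
    a2[i] <- flag(i, 2L, "6mA")
  }
  inst$m5c_pos3 <- m5; inst$m6a_pos1 <- a1; inst$m6a_pos2 <- a2
  inst$category <- methylation_category(m5, a1, a2)
  tally_census(inst, promoters)
}

#' Generate a set of simulated thermograms over a parameter grid
#'
#' Delegates to [simulate_titration()] for each row of the grid x replicate,
#' recording every true parameter set.
#'
#' @param grid `data.frame` with columns `n`, `Kd`, `dH` and optionally `q0`.
#' @param protocol [itc_protocol()].
#' @param noise_sd Gaussian noise s.d. (ucal).
#' @param reps Replicates per grid row.
#' @param seed RNG seed (local); each thermogram gets a distinct derived
#'   stream.
#' @param out_dir Optional directory; writes `itc_<row>_<rep>.tsv` and
#'   `itc_truth.json`.
#' @return List of class `"synthetic_itc"`: `$thermograms` (list),
#'   `$truth` (grid with `row`, `rep` indices), `$paths` when written.
#' @export
gen_thermograms <- function(grid, protocol = itc_protocol(), noise_sd = 0,
                            reps = 1L, seed = 1L, out_dir = NULL) {
  if (is.null(grid$q0)) grid$q0 <- 0
  tgs <- list()
  truth <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(grid))) for (j in seq_len(reps)) {
      p <- binding_params(grid$n[r], grid$Kd[r], grid$dH[r], grid$q0[r])
      tg <- simulate_titration(p, protocol, noise_sd = noise_sd)
      tgs[[length(tgs) + 1L]] <- tg
      truth[[length(truth) + 1L]] <- data.frame(
        row = r, rep = j, n = grid$n[r], Kd = grid$Kd[r], dH = grid$dH[r],
        q0 = grid$q0[r], noise_sd = noise_sd)
    }
  })
  truth <- do.call(rbind, truth)
  out <- list(thermograms = tgs, truth = truth,
              protocol = protocol, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(length(tgs))
    for (k in seq_along(tgs))
      paths[k] <- write_thermogram(tgs[[k]], file.path(
        out_dir, sprintf("itc_%03d_%02d.tsv", truth$row[k], truth$rep[k])))
    tj <- file.path(out_dir, "itc_truth.json")
    jsonlite::write_json(list(truth = truth, seed = seed), tj,
                         auto_unbox = TRUE, digits = NA)
    out$paths <- list(thermograms = paths, truth = tj)
  }
  class(out) <- "synthetic_itc"
  out
}
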