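# Degenerate-motif scanning over genomes and promoter windows.
#
# Two independent routes are provided: scan_motifs() (Biostrings-based, the
# production path) and scan_motifs_naive() (plain-string regex enumeration, a
# reference implementation kept deliberately free of Biostrings so the two
# can validate each other).

#' Scan a genome for a degenerate motif
#'
#' Finds every occurrence of an IUPAC pattern on the requested strand(s).
#' Minus-strand occurrences are located by matching the reverse-complemented
#' pattern and are reported in genomic coordinates with `strand == "-"`;
#' `matched_seq` is always the motif-strand sequence.  A genomic `N` matches
#' no pattern symbol (including pattern `N`), so unknown sequence never
#' creates phantom motifs.
#'
#' When promoter `windows` are supplied, only instances lying entirely inside
#' at least one window are reported (each occurrence once, even when windows
#' overlap), and `gene_ids` lists every gene whose window overlaps the
#' instance, comma-separated.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [load_genome()]).
#' @param pattern IUPAC pattern string, e.g. `"AACNDN"`.
#' @param windows Optional promoter table from [derive_promoters()].
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `matched_seq`, `gene_ids`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(probe = "AAATTCTCCAACCGCATTTTC"))
#' scan_motifs(g, "AACNDN")
#' @export
scan_motifs <- function(genome, pattern, windows = NULL,
                        strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  pattern <- motif_pattern(pattern)
  pat <- Biostrings::DNAString(unclass(pattern))
  plen <- nchar(pattern)
  res <- list()
  for (ch in names(genome)) {
    subject <- genome[[ch]]
    if (strands %in% c("both", "+")) {
      m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
      if (length(m)) {
        seqs <- as.character(m)
        keep <- !grepl("N", seqs, fixed = TRUE)
        if (any(keep))
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, start = Biostrings::start(m)[keep] - 1L,
            end = Biostrings::end(m)[keep], strand = "+",
            matched_seq = seqs[keep], stringsAsFactors = FALSE)
      }
    }
    if (strands %in% c("both", "-")) {
      m <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = FALSE)
      if (length(m)) {
        slice <- as.character(m)
        keep <- !grepl("N", slice, fixed = TRUE)
        if (any(keep))
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, start = Biostrings::start(m)[keep] - 1L,
            end = Biostrings::end(m)[keep], strand = "-",
            matched_seq = revcomp_chr(slice[keep]), stringsAsFactors = FALSE)
      }
    }
  }
  inst <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), matched_seq = character(),
               stringsAsFactors = FALSE)
  inst <- inst[order(inst$chrom, inst$start, inst$strand), , drop = FALSE]
  inst$gene_ids <- rep(NA_character_, nrow(inst))
  if (!is.null(windows) && nrow(inst)) {
    inst <- restrict_to_windows(inst, windows)
  } else if (!is.null(windows)) {
    inst <- inst[0L, , drop = FALSE]
  }
  rownames(inst) <- NULL
  attr(inst, "pattern") <- unclass(pattern)
  class(inst) <- c("motif_instances", "data.frame")
  inst
}

# Keep instances fully contained in >= 1 window; credit genes whose windows
# overlap the instance at all.
restrict_to_windows <- function(inst, windows) {
  igr <- GenomicRanges::GRanges(inst$chrom,
                                IRanges::IRanges(inst$start + 1L, inst$end))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end))
  within <- GenomicRanges::countOverlaps(igr, wgr, type = "within") > 0L
  inst <- inst[within, , drop = FALSE]
  if (!nrow(inst)) return(inst)
  igr <- igr[within]
  ov <- GenomicRanges::findOverlaps(igr, wgr, type = "any")
  gid <- split(windows$gene_id[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov))
  ids <- rep(NA_character_, nrow(inst))
  idx <- as.integer(names(gid))
  ids[idx] <- vapply(gid, function(g)
    paste(sort(unique(g)), collapse = ","), character(1L))
  inst$gene_ids <- ids
  inst
}

#' Naive reference motif scanner
#'
#' Independent enumeration-based implementation of [scan_motifs()] operating
#' on plain character strings with a Perl lookahead regex, used to
#' cross-validate the production scanner.  Semantics are identical (genomic
#' `N` matches nothing; minus-strand hits reported in genomic coordinates;
#' window containment and gene credit as in [scan_motifs()]).
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param pattern IUPAC pattern string.
#' @param windows Optional promoter table.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return Same shape as [scan_motifs()].
#' @export
scan_motifs_naive <- function(seqs, pattern, windows = NULL,
                              strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  pattern <- motif_pattern(pattern)
  plen <- nchar(pattern)
  rx <- paste0("(?=", pattern_regex(pattern), ")")
  scan_one <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m)  # 1-based starts
  }
  rows <- list()
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    if (strands %in% c("both", "+")) {
      st <- scan_one(s)
      for (p in st)
        rows[[length(rows) + 1L]] <- list(chrom = ch, start = p - 1L,
          end = p - 1L + plen, strand = "+",
          matched_seq = substring(s, p, p + plen - 1L))
    }
    if (strands %in% c("both", "-")) {
      rc <- revcomp_chr(s)
      L <- nchar(s)
      st <- scan_one(rc)
      for (p in st) {
        # position p on revcomp corresponds to genomic [L-p-plen+1, L-p+1)
        g0 <- L - (p - 1L) - plen
        rows[[length(rows) + 1L]] <- list(chrom = ch, start = g0,
          end = g0 + plen, strand = "-",
          matched_seq = substring(rc, p, p + plen - 1L))
      }
    }
  }
  inst <- if (length(rows))
    do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  strand = character(), matched_seq = character(),
                  stringsAsFactors = FALSE)
  inst <- inst[order(inst$chrom, inst$start, inst$strand), , drop = FALSE]
  inst$gene_ids <- rep(NA_character_, nrow(inst))
  if (!is.null(windows)) {
    if (nrow(inst)) {
      wsplit <- split(windows[c("start", "end", "gene_id")], windows$chrom)
      keep <- logical(nrow(inst))
      ids <- rep(NA_character_, nrow(inst))
      for (i in seq_len(nrow(inst))) {
        w <- wsplit[[inst$chrom[i]]]
        if (is.null(w)) next
        contained <- w$start <= inst$start[i] & inst$end[i] <= w$end
        keep[i] <- any(contained)
        if (keep[i]) {
          overlaps <- w$start < inst$end[i] & inst$start[i] < w$end
          ids[i] <- paste(sort(unique(w$gene_id[overlaps])), collapse = ",")
        }
      }
      inst <- inst[keep, , drop = FALSE]
      inst$gene_ids <- ids[keep]
    }
  }
  rownames(inst) <- NULL
  attr(inst, "pattern") <- unclass(pattern)
  inst
}
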