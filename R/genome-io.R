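# Readers for the flat-file inputs of the census stage: genome FASTA, gene
# annotation (GFF3 or BED6) and single-base methylation calls.
#
# Coordinate convention: all data frames in this package use 0-based
# half-open intervals (BED semantics).  GFF3 (1-based closed) is converted on
# read.

#' Load a genome from a FASTA file
#'
#' Reads a multi-record FASTA, uppercases the sequences and validates the
#' alphabet (`A`, `C`, `G`, `T`, `N` only).  Duplicate record names are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtn"), fa)
#' load_genome(fa)
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first) || !startsWith(lines[first], ">"))
    stop("malformed FASTA: line ", if (is.na(first)) 1L else first,
         " is not a header line")
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  # header names: first whitespace token
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  genome <- Biostrings::DNAStringSet(toupper(genome))
  bad <- Biostrings::letterFrequency(genome, letters = "ACGTN")
  extra <- Biostrings::width(genome) - rowSums(bad)
  if (any(extra > 0))
    stop("sequence(s) contain letters outside {A,C,G,T,N}: ",
         paste(names(genome)[extra > 0], collapse = ", "))
  genome
}

#' Load a gene annotation (GFF3 or BED6)
#'
#' GFF3 files are filtered to `gene` features and converted from 1-based
#' closed to 0-based half-open coordinates; BED6 files are read as-is.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    if (!length(gr)) stop("no gene features found in ", path)
    ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$Name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
    ann <- data.frame(
      gene_id = as.character(ids),
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      start   = GenomicRanges::start(gr) - 1L,
      end     = GenomicRanges::end(gr),
      strand  = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    ann <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "gene_id",
                                    "score", "strand")[1:6])
    ann <- ann[, c("gene_id", "chrom", "start", "end", "strand")]
  }
  if (any(!ann$strand %in% c("+", "-")))
    stop("annotation contains genes without +/- strand")
  if (any(ann$start < 0L | ann$start >= ann$end))
    stop("annotation contains invalid gene spans")
  ann
}

#' Derive upstream promoter windows from gene spans
#'
#' The promoter of a gene is the `upstream_length` bp immediately 5' of its
#' transcription start site: `[start - L, start)` for `+` genes and
#' `[end, end + L)` for `-` genes, clipped to the chromosome.  Genes whose
#' window is empty after clipping (TSS at a chromosome edge) are dropped with
#' a warning.
#'
#' @param annotation Gene table as returned by [load_annotation()].
#' @param genome A [Biostrings::DNAStringSet] (for chromosome lengths) or a
#'   named integer vector of chromosome lengths.
#' @param upstream_length Window length in bp upstream of the TSS
#'   (default 3000).
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open).
#' @examples
#' ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000,
#'                   end = 8000, strand = "+")
#' derive_promoters(ann, c(chr1 = 20000L))
#' @export
derive_promoters <- function(annotation, genome, upstream_length = 3000L) {
  stopifnot(upstream_length >= 1L)
  lens <- if (methods::is(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome)) else genome
  unknown <- setdiff(unique(annotation$chrom), names(lens))
  if (length(unknown))
    stop("annotation references unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  L <- as.integer(upstream_length)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$start - L, annotation$end)
  end   <- ifelse(plus, annotation$start,     annotation$end + L)
  clen  <- unname(lens[annotation$chrom])
  start <- pmax(start, 0L)
  end   <- pmin(end, clen)
  keep  <- start < end
  if (any(!keep))
    warning(sum(!keep), " gene(s) dropped: empty promoter window at ",
            "chromosome edge (", paste(annotation$gene_id[!keep],
                                       collapse = ", "), ")")
  data.frame(
    gene_id = annotation$gene_id[keep],
    chrom   = annotation$chrom[keep],
    strand  = annotation$strand[keep],
    start   = as.integer(start[keep]),
    end     = as.integer(end[keep]),
    stringsAsFactors = FALSE
  )
}

#' Load single-base methylation calls from a BED-like file
#'
#' Accepts whitespace- or tab-delimited records `chrom start end [name]
#' [score] strand` describing one modified base each (`end == start + 1`
#' enforced, with the offending line cited otherwise).  Calls are
#' strand-specific; duplicates at `(chrom, pos, strand)` are removed.
#'
#' @param path Path to the calls file.
#' @param mod_type `"5mC"` or `"6mA"`; attached to every call.
#' @param min_score Optional minimum score; rows below it are dropped.
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, calls
#'   whose strand-resolved base is not chemically valid (`C` for 5mC, `A` for
#'   6mA) are dropped with a warning.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `mod_type`, `score`.
#' @export
load_methylation <- function(path, mod_type, min_score = NULL, genome = NULL) {
  mod_type <- match.arg(mod_type, c("5mC", "6mA"))
  if (!file.exists(path)) stop("methylation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                        !startsWith(lines, "track"))
  if (!length(lines_keep))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), mod_type = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[lines_keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("methylation file '", path, "': line ", lines_keep[which(nf < 3L)[1L]],
         " has fewer than 3 columns")
  parse_row <- function(f, line_no) {
    start <- suppressWarnings(as.integer(f[2L]))
    end   <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop("methylation file '", path, "': line ", line_no,
           " has non-numeric coordinates")
    if (end != start + 1L)
      stop("methylation file '", path, "': line ", line_no,
           " is not a single-base record (end != start + 1)")
    n <- length(f)
    strand <- f[n]
    if (!strand %in% c("+", "-"))
      stop("methylation file '", path, "': line ", line_no,
           " has no +/- strand in the last column")
    score <- if (n >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_
    list(chrom = f[1L], pos = start, strand = strand, score = score)
  }
  rows <- Map(parse_row, fields, lines_keep)
  calls <- data.frame(
    chrom  = vapply(rows, `[[`, character(1L), "chrom"),
    pos    = vapply(rows, `[[`, integer(1L), "pos"),
    strand = vapply(rows, `[[`, character(1L), "strand"),
    mod_type = mod_type,
    score  = vapply(rows, `[[`, numeric(1L), "score"),
    stringsAsFactors = FALSE
  )
  if (!is.null(min_score)) {
    keep <- !is.na(calls$score) & calls$score >= min_score
    calls <- calls[keep, , drop = FALSE]
  }
  if (!is.null(genome)) {
    want <- if (mod_type == "5mC") "C" else "A"
    base <- base_at(genome, calls$chrom, calls$pos, calls$strand)
    ok <- base == want
    if (any(!ok)) {
      warning(sum(!ok), " ", mod_type, " call(s) dropped: genome base is not ",
              want, " on the call strand")
      calls <- calls[ok, , drop = FALSE]
    }
  }
  calls <- calls[!duplicated(calls[c("chrom", "pos", "strand", "mod_type")]),
                 , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

# Strand-resolved base at 0-based position(s): the base read on `strand`.
base_at <- function(genome, chrom, pos, strand) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (!ch %in% names(genome)) stop("unknown chromosome in calls: ", ch)
    s <- as.character(genome[[ch]])
    b <- substring(s, pos[i] + 1L, pos[i] + 1L)
    minus <- strand[i] == "-"
    b[minus] <- unname(COMPLEMENT[b[minus]])
    out[i] <- b
  }
  out
}
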