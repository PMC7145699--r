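# IUPAC nucleotide codes and small shared helpers.

# Base sets for every IUPAC code.  Genome `N` is treated as an unknown base
# that matches no pattern code (see scan_motifs); these sets describe pattern
# symbols only.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B"
)

#' Validate a degenerate motif pattern
#'
#' Checks that every symbol is a defined IUPAC nucleotide code and returns the
#' uppercased pattern with class `"motif_pattern"`.
#'
#' @param x Single character string of IUPAC codes, e.g. `"AACNDN"`.
#' @return The validated pattern string, classed `"motif_pattern"`.
#' @examples
#' motif_pattern("AACNDN")
#' @export
motif_pattern <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop("pattern must be a single non-empty string")
  x <- toupper(x)
  sym <- strsplit(x, "")[[1L]]
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in pattern: ", paste(unique(bad), collapse = ", "))
  structure(x, class = "motif_pattern")
}

# Reverse complement of a plain character DNA/IUPAC string (string-level,
# independent of Biostrings; used by the naive reference scanner).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    paste(rev(unname(COMPLEMENT[strsplit(toupper(s), "")[[1L]]])), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Perl regex character classes for a pattern; genome N must not match, so N is
# never included in the classes.
pattern_regex <- function(pattern) {
  sym <- strsplit(unclass(motif_pattern(pattern)), "")[[1L]]
  paste(vapply(sym, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# Does a concrete sequence match the pattern position-wise?
matches_pattern <- function(seq, pattern) {
  seq <- toupper(seq)
  pat <- unclass(motif_pattern(pattern))
  if (nchar(seq) != nchar(pat)) return(FALSE)
  grepl(paste0("^", pattern_regex(pat), "$"), seq, perl = TRUE)
}

# Deterministic local RNG scope: run `expr` under `seed` without clobbering
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
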