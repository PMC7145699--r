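# Strand-aware intersection of motif instances with per-base methylation
# calls, and the category census over the AAC core.
#
# Motif position k (1-based, counted along the motif strand) maps to genomic
# coordinate start + k - 1 for "+" instances and end - k for "-" instances,
# and a call only counts when its strand equals the motif strand: 5mC and
# 6mA are per-strand chemical marks.

CENSUS_CATEGORIES <- c(
  "unmethylated", "5mC-only", "6mA1-only", "6mA2-only",
  "5mC+6mA1", "5mC+6mA2", "6mA1+6mA2", "5mC+6mA1+6mA2"
)

# Category from the three flags (pure function).
methylation_category <- function(m5c_pos3, m6a_pos1, m6a_pos2) {
  ifelse(!m5c_pos3 & !m6a_pos1 & !m6a_pos2, "unmethylated",
  ifelse( m5c_pos3 & !m6a_pos1 & !m6a_pos2, "5mC-only",
  ifelse(!m5c_pos3 &  m6a_pos1 & !m6a_pos2, "6mA1-only",
  ifelse(!m5c_pos3 & !m6a_pos1 &  m6a_pos2, "6mA2-only",
  ifelse( m5c_pos3 &  m6a_pos1 & !m6a_pos2, "5mC+6mA1",
  ifelse( m5c_pos3 & !m6a_pos1 &  m6a_pos2, "5mC+6mA2",
  ifelse(!m5c_pos3 &  m6a_pos1 &  m6a_pos2, "6mA1+6mA2",
         "5mC+6mA1+6mA2")))))))
}

# Genomic 0-based coordinate of motif position k (1-based) for instance rows.
motif_position_coord <- function(start, end, strand, k) {
  ifelse(strand == "+", start + k - 1L, end - k)
}

#' Attach methylation calls to motif instances
#'
#' Flags each instance for 5mC at motif position 3 (the C of the AAC core)
#' and 6mA at motif positions 1 and 2 (the two As), requiring the call to lie
#' on the motif strand, and derives the 8-way methylation category.
#'
#' @param instances Output of [scan_motifs()].
#' @param calls Methylation calls from [load_methylation()] (rows of both
#'   modification types may be concatenated).
#' @return The instance table with added logical columns `m5c_pos3`,
#'   `m6a_pos1`, `m6a_pos2` and character `category`.
#' @export
attach_methylation <- function(instances, calls) {
  inst <- as.data.frame(instances)
  if (is.null(calls) || !nrow(calls)) {
    inst$m5c_pos3 <- logical(nrow(inst))
    inst$m6a_pos1 <- logical(nrow(inst))
    inst$m6a_pos2 <- logical(nrow(inst))
  } else {
    key <- function(chrom, pos, strand, type)
      paste(chrom, pos, strand, type, sep = ":")
    callset <- key(calls$chrom, calls$pos, calls$strand, calls$mod_type)
    flag_at <- function(k, type) {
      pos <- motif_position_coord(inst$start, inst$end, inst$strand, k)
      key(inst$chrom, pos, inst$strand, type) %in% callset
    }
    inst$m5c_pos3 <- flag_at(3L, "5mC")
    inst$m6a_pos1 <- flag_at(1L, "6mA")
    inst$m6a_pos2 <- flag_at(2L, "6mA")
  }
  inst$category <- methylation_category(inst$m5c_pos3, inst$m6a_pos1,
                                        inst$m6a_pos2)
  class(inst) <- c("motif_methylation", "data.frame")
  inst
}

#' Tally the motif--methylation census
#'
#' Summarizes records from [attach_methylation()]: total instances, distinct
#' genes carrying at least one instance, the count of each of the 8
#' methylation categories, and the marginal counts (any methylation, 5mC at
#' position 3, 6mA at positions 1 and 2).
#'
#' @param records Output of [attach_methylation()].
#' @param promoters Optional promoter table (adds `n_promoters` context to
#'   the printout).
#' @return A list of class `"motif_census"`.
#' @export
tally_census <- function(records, promoters = NULL) {
  cat_counts <- setNames(integer(length(CENSUS_CATEGORIES)), CENSUS_CATEGORIES)
  tab <- table(factor(records$category, levels = CENSUS_CATEGORIES))
  cat_counts[names(tab)] <- as.integer(tab)
  genes <- unlist(strsplit(records$gene_ids[!is.na(records$gene_ids)], ","))
  out <- list(
    total = nrow(records),
    n_genes = length(unique(genes)),
    categories = cat_counts,
    any_methylated = nrow(records) - unname(cat_counts["unmethylated"]),
    m5c_pos3 = sum(records$m5c_pos3),
    m6a_pos1 = sum(records$m6a_pos1),
    m6a_pos2 = sum(records$m6a_pos2),
    n_promoters = if (is.null(promoters)) NA_integer_ else nrow(promoters)
  )
  class(out) <- "motif_census"
  out
}

#' @export
print.motif_census <- function(x, ...) {
  cat("Motif-methylation census\n")
  cat(sprintf("  motif instances: %d (in %d genes%s)\n", x$total, x$n_genes,
              if (is.na(x$n_promoters)) ""
              else sprintf(" of %d promoters", x$n_promoters)))
  cat(sprintf("  methylated: %d (5mC@3: %d, 6mA@1: %d, 6mA@2: %d)\n",
              x$any_methylated, x$m5c_pos3, x$m6a_pos1, x$m6a_pos2))
  for (nm in names(x$categories))
    cat(sprintf("    %-14s %d\n", nm, x$categories[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.motif_census <- function(x, ...) {
  data.frame(category = names(x$categories),
             count = unname(x$categories),
             stringsAsFactors = FALSE)
}

#' Write a census as TSV
#'
#' @param census A `"motif_census"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  df <- rbind(
    data.frame(metric = c("total", "n_genes", "any_methylated",
                          "m5c_pos3", "m6a_pos1", "m6a_pos2"),
               count = c(census$total, census$n_genes, census$any_methylated,
                         census$m5c_pos3, census$m6a_pos1, census$m6a_pos2)),
    data.frame(metric = paste0("category:", names(census$categories)),
               count = unname(census$categories))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif instances as BED6
#'
#' The name field is `matched_seq;category` when categories are present.
#'
#' @param records Output of [scan_motifs()] or [attach_methylation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_instances_bed <- function(records, path) {
  name <- if ("category" %in% names(records))
    paste(records$matched_seq, records$category, sep = ";")
  else records$matched_seq
  bed <- data.frame(records$chrom, records$start, records$end,
                    name, 0L, records$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-column residue frequencies of a protein alignment
#'
#' For each requested alignment column, counts the residues observed across
#' sequences; frequencies are over non-gap characters and sum to 1, with the
#' gap fraction reported separately.
#'
#' @param msa An [Biostrings::AAStringSet], named character vector, or path
#'   to an aligned FASTA.  All sequences must have equal length.
#' @param columns Integer vector of 1-based alignment columns
#'   (default: all).
#' @return List of class `"consensus_profile"` with `$frequencies`
#'   (`data.frame`: `column`, `residue`, `count`, `freq`) and
#'   `$gap_fraction` (named by column).
#' @export
consensus_profile <- function(msa, columns = NULL) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  seqs <- toupper(as.character(msa))
  if (!length(seqs)) stop("empty alignment")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  width <- nchar(seqs[[1L]])
  if (is.null(columns)) columns <- seq_len(width)
  if (any(columns < 1L | columns > width))
    stop("requested column(s) outside alignment width ", width)
  mat <- do.call(rbind, strsplit(seqs, ""))
  freq_rows <- list()
  gapf <- setNames(numeric(length(columns)), columns)
  for (i in seq_along(columns)) {
    col <- mat[, columns[i]]
    gap <- col %in% c("-", ".")
    gapf[i] <- mean(gap)
    obs <- col[!gap]
    if (length(obs)) {
      tab <- sort(table(obs), decreasing = TRUE)
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        column = columns[i], residue = names(tab),
        count = as.integer(tab), freq = as.numeric(tab) / length(obs),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(
    frequencies = if (length(freq_rows)) do.call(rbind, freq_rows) else
      data.frame(column = integer(), residue = character(),
                 count = integer(), freq = numeric()),
    gap_fraction = gapf
  )
  class(out) <- "consensus_profile"
  out
}
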