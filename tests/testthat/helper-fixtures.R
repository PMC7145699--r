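# Shared test helpers: small file builders and brute-force oracles kept
# deliberately simple (plain loops, plain strings) so they are independent of
# the vectorized production code paths.

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

write_bed_calls <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d\t.\t%s\t%s", df$chrom, df$pos, df$pos + 1L,
                     ifelse(is.na(df$score), "0", as.character(df$score)),
                     df$strand), path)
  path
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(.24, .24, .24, .24, .04) else rep(.25, 4)
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

# All-pairs brute-force contact finder over a structure_model, mirroring the
# documented chemistry rules with explicit loops.
bf_contacts <- function(model, d_hb = 3.5, d_ap = 4.5) {
  chem <- chemistry_table()
  role_of <- function(res, atom) {
    r <- chem$role[chem$res == res & chem$atom == atom]
    if (length(r)) r[1L] else "none"
  }
  at <- model$atoms
  prot <- at[at$class == "protein", ]
  dna <- at[at$class == "nucleic", ]
  out <- list()
  for (i in seq_len(nrow(prot))) for (j in seq_len(nrow(dna))) {
    d <- sqrt((prot$x[i] - dna$x[j])^2 + (prot$y[i] - dna$y[j])^2 +
                (prot$z[i] - dna$z[j])^2)
    pr <- role_of(prot$resid[i], prot$atom[i])
    dr <- role_of(dna$resid[j], dna$atom[j])
    polar <- c("donor", "acceptor", "both")
    hb <- d <= d_hb && pr %in% polar && dr %in% polar &&
      ((pr != "acceptor" && dr != "donor") ||
         (pr != "donor" && dr != "acceptor"))
    ap <- d <= d_ap && pr == "apolar" && dr == "apolar"
    if (hb || ap)
      out[[length(out) + 1L]] <- data.frame(
        protein_resno = prot$resno[i], protein_atom = prot$atom[i],
        dna_resno = dna$resno[j], dna_atom = dna$atom[j],
        distance = round(d, 3), kind = if (hb) "direct-hbond"
        else "apolar-proximity", stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(protein_resno = integer(), protein_atom = character(),
               dna_resno = integer(), dna_atom = character(),
               distance = numeric(), kind = character())
}

contact_key <- function(df)
  sort(paste(df$protein_resno, df$protein_atom, df$dna_resno, df$dna_atom,
             df$kind, round(df$distance, 2)))
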