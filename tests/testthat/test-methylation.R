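# Strand-aware flag attachment, category census and MSA consensus profile.

mk_inst <- function(chrom = "c1", start, end, strand, seq = "AACCGC",
                    gene = "g1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             matched_seq = seq, gene_ids = gene, stringsAsFactors = FALSE)
}

mk_call <- function(chrom = "c1", pos, strand, type) {
  data.frame(chrom = chrom, pos = pos, strand = strand, mod_type = type,
             score = 1, stringsAsFactors = FALSE)
}

test_that("motif position coordinates map correctly on both strands", {
  # + instance at [9,15): position 3 is genomic 11
  rec <- attach_methylation(mk_inst(start = 9L, end = 15L, strand = "+"),
                            mk_call(pos = 11L, strand = "+", type = "5mC"))
  expect_true(rec$m5c_pos3)
  expect_equal(rec$category, "5mC-only")

  # - instance at [9,15): position 1 is genomic 14, position 3 genomic 12
  rec <- attach_methylation(mk_inst(start = 9L, end = 15L, strand = "-"),
                            rbind(mk_call(pos = 14L, strand = "-", type = "6mA"),
                                  mk_call(pos = 12L, strand = "-", type = "5mC")))
  expect_true(rec$m6a_pos1)
  expect_true(rec$m5c_pos3)
  expect_false(rec$m6a_pos2)
  expect_equal(rec$category, "5mC+6mA1")

  # brute-force check of the base identity at the mapped coordinate: a minus
  # instance of AACCGC at [9,15) means plus-strand slice GCGGTT, whose last
  # base (genomic 14) pairs with the motif's first A
  s <- paste0(strrep("T", 9), "GCGGTT", strrep("T", 6))
  base_plus <- substring(s, 15, 15)
  expect_equal(base_plus, "T")   # so the minus-strand base is A, a 6mA site
})

test_that("calls on the wrong strand or wrong position do not flag", {
  inst <- mk_inst(start = 9L, end = 15L, strand = "+")
  rec <- attach_methylation(inst,
                            mk_call(pos = 11L, strand = "-", type = "5mC"))
  expect_false(rec$m5c_pos3)
  rec <- attach_methylation(inst,
                            mk_call(pos = 12L, strand = "+", type = "5mC"))
  expect_false(rec$m5c_pos3)
  rec <- attach_methylation(inst, NULL)
  expect_equal(rec$category, "unmethylated")
})

test_that("category is a pure function of the three flags", {
  grid <- expand.grid(m5 = c(FALSE, TRUE), a1 = c(FALSE, TRUE),
                      a2 = c(FALSE, TRUE))
  cats <- mybdna:::methylation_category(grid$m5, grid$a1, grid$a2)
  expect_setequal(cats, mybdna:::CENSUS_CATEGORIES)
  expect_equal(cats[1], "unmethylated")
  expect_equal(cats[8], "5mC+6mA1+6mA2")
})

test_that("census counts are conserved and marginally consistent", {
  set.seed(5)
  n <- 200
  inst <- mk_inst(start = seq(0L, by = 10L, length.out = n),
                  end = seq(6L, by = 10L, length.out = n),
                  strand = sample(c("+", "-"), n, TRUE),
                  gene = sample(c("g1", "g2", "g3"), n, TRUE))
  flags <- data.frame(m5 = runif(n) < .3, a1 = runif(n) < .1,
                      a2 = runif(n) < .2)
  calls <- list()
  for (i in seq_len(n)) {
    coord <- function(k) mybdna:::motif_position_coord(
      inst$start[i], inst$end[i], inst$strand[i], k)
    if (flags$m5[i]) calls[[length(calls) + 1L]] <-
      mk_call(pos = coord(3L), strand = inst$strand[i], type = "5mC")
    if (flags$a1[i]) calls[[length(calls) + 1L]] <-
      mk_call(pos = coord(1L), strand = inst$strand[i], type = "6mA")
    if (flags$a2[i]) calls[[length(calls) + 1L]] <-
      mk_call(pos = coord(2L), strand = inst$strand[i], type = "6mA")
  }
  rec <- attach_methylation(inst, do.call(rbind, calls))
  expect_equal(rec$m5c_pos3, flags$m5)
  expect_equal(rec$m6a_pos1, flags$a1)
  expect_equal(rec$m6a_pos2, flags$a2)
  cen <- tally_census(rec)
  expect_equal(sum(cen$categories), cen$total)
  expect_equal(cen$any_methylated, cen$total - cen$categories[["unmethylated"]])
  with5 <- grepl("5mC", names(cen$categories))
  expect_equal(cen$m5c_pos3, sum(cen$categories[with5]))
  expect_equal(cen$m6a_pos1,
               sum(cen$categories[grepl("6mA1", names(cen$categories))]))
  expect_lte(cen$n_genes, 3L)
})

test_that("empty records give an all-zero census", {
  rec <- attach_methylation(mk_inst(start = 1L, end = 7L, strand = "+")[0, ],
                            NULL)
  cen <- tally_census(rec)
  expect_equal(cen$total, 0L)
  expect_equal(sum(cen$categories), 0L)
  expect_equal(cen$n_genes, 0L)
})

test_that("consensus_profile counts residues and gaps per column", {
  msa <- c(s1 = "LKDE", s2 = "LKDE", s3 = "EK-E", s4 = "EK.E")
  cp <- consensus_profile(msa)
  col1 <- cp$frequencies[cp$frequencies$column == 1, ]
  expect_equal(sort(col1$freq), c(0.5, 0.5))
  expect_setequal(col1$residue, c("L", "E"))
  expect_equal(sum(col1$freq), 1)
  expect_equal(unname(cp$gap_fraction[["3"]]), 0.5)

  one <- consensus_profile(c(s = "M"))
  expect_equal(one$frequencies$freq, 1)

  gaps <- consensus_profile(c(a = "-", b = "-"))
  expect_equal(nrow(gaps$frequencies), 0L)
  expect_equal(unname(gaps$gap_fraction[["1"]]), 1)

  expect_error(consensus_profile(c(a = "AB", b = "A")), "ragged")
  expect_error(consensus_profile(c(a = "AB"), columns = 5), "outside")
})
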