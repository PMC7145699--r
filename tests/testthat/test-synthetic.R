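# Synthetic-data generators: determinism, planted truth, statistical
# calibration.

test_that("gen_genome is deterministic and writes byte-identical files", {
  d1 <- file.path(tempdir(), "sg1"); d2 <- file.path(tempdir(), "sg2")
  s1 <- gen_genome(chrom_len = 20000L, n_genes = 3L, n_planted = 5L,
                   seed = 7, out_dir = d1)
  s2 <- gen_genome(chrom_len = 20000L, n_genes = 3L, n_planted = 5L,
                   seed = 7, out_dir = d2)
  for (f in c("genome.fa", "genes.gff3", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  s3 <- gen_genome(chrom_len = 20000L, n_genes = 3L, n_planted = 5L,
                   seed = 8)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("gc = 0 yields an all-A/T background", {
  s <- gen_genome(chrom_len = 10000L, n_genes = 1L, n_planted = 0L,
                  gc = 0, seed = 1)
  freq <- Biostrings::letterFrequency(s$genome, c("G", "C"))
  expect_equal(sum(freq), 0L)
})

test_that("planted motifs are recovered by the scanner and match truth", {
  s <- gen_genome(chrom_len = 30000L, n_genes = 3L, n_planted = 5L, seed = 7)
  inst <- scan_motifs(s$genome, "AACNDN", windows = s$promoters)
  pk <- with(s$truth$planted, paste(chrom, start, strand))
  ik <- with(inst, paste(chrom, start, strand))
  expect_true(all(pk %in% ik))
  # planted sequences match the pattern and the genome slice
  for (i in seq_len(nrow(s$truth$planted))) {
    p <- s$truth$planted[i, ]
    expect_true(mybdna:::matches_pattern(p$seq, "AACNDN"))
    slice <- as.character(Biostrings::subseq(s$genome[[p$chrom]],
                                             p$start + 1L, p$end))
    expect_equal(if (p$strand == "+") slice else
      mybdna:::revcomp_chr(slice), p$seq)
  }
})

test_that("methylome generator respects degenerate rates and saturation", {
  s <- gen_genome(chrom_len = 30000L, n_genes = 3L, n_planted = 10L, seed = 3)
  off <- gen_methylome(s, 0, 0, 0, 0, seed = 4)
  expect_equal(nrow(off$calls), 0L)
  expect_false(any(off$flags$m5c_pos3))

  sat <- gen_methylome(s, 1, 0, 0, 0, seed = 4)
  expect_true(all(sat$flags$m5c_pos3))
  inst <- scan_motifs(s$genome, "AACNDN", windows = s$promoters)
  rec <- attach_methylation(inst, sat$calls)
  planted_keys <- with(s$truth$planted, paste(chrom, start, strand))
  rec_planted <- rec[paste(rec$chrom, rec$start, rec$strand) %in% planted_keys, ]
  expect_true(all(rec_planted$m5c_pos3))
})

test_that("flag draws fall inside binomial 99% bounds at n = 2000", {
  s <- gen_genome(chrom_len = 1000000L, n_genes = 100L, n_planted = 2000L,
                  seed = 31)
  m <- gen_methylome(s, p_5mC_pos3 = 0.1, p_6mA_pos1 = 0.005,
                     p_6mA_pos2 = 0.015, p_background = 0, seed = 3)
  n <- nrow(m$flags)
  expect_equal(n, 2000L)
  for (spec in list(list(col = "m5c_pos3", p = 0.1),
                    list(col = "m6a_pos1", p = 0.005),
                    list(col = "m6a_pos2", p = 0.015))) {
    k <- sum(m$flags[[spec$col]])
    lo <- qbinom(0.005, n, spec$p)
    hi <- qbinom(0.995, n, spec$p)
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
})

test_that("background calls land only on chemically valid bases", {
  s <- gen_genome(chrom_len = 20000L, n_genes = 2L, n_planted = 0L, seed = 5)
  m <- gen_methylome(s, 0, 0, 0, p_background = 0.01, seed = 6)
  expect_gt(nrow(m$calls), 0L)
  base <- mybdna:::base_at(s$genome, m$calls$chrom, m$calls$pos,
                           m$calls$strand)
  expect_true(all(base[m$calls$mod_type == "5mC"] == "C"))
  expect_true(all(base[m$calls$mod_type == "6mA"] == "A"))
})

test_that("fixture truth records exactly what the contact engine finds", {
  fx <- wer_interface_fixture()
  m <- parse_structure(fx$path)
  ct <- find_contacts(m)
  expect_equal(nrow(ct), nrow(fx$truth))
  key <- function(df) sort(paste(df$protein_res, df$protein_atom,
                                 df$dna_res, df$dna_resno, df$dna_atom,
                                 df$kind))
  expect_identical(key(ct), key(fx$truth))
  # planted distances are realized to 0.01 A
  mct <- merge(ct, fx$truth,
               by = c("protein_res", "protein_atom", "dna_res",
                      "dna_resno", "dna_atom"))
  expect_true(all(abs(mct$distance.x - mct$distance.y) < 0.01))
})

test_that("empty fixture spec yields a valid empty file", {
  fx <- build_fixture(list())
  expect_true(file.exists(fx$path))
  expect_equal(nrow(fx$atoms), 0L)
  expect_null(fx$truth)
})

test_that("gen_thermograms records truth for every grid cell and rep", {
  grid <- data.frame(n = c(1, 1), Kd = c(0.05, 0.5), dH = c(-8000, -6000))
  g <- gen_thermograms(grid, reps = 3L, noise_sd = 0.02, seed = 11)
  expect_length(g$thermograms, 6L)
  expect_equal(nrow(g$truth), 6L)
  expect_equal(g$truth$Kd, rep(grid$Kd, each = 3L))
  g2 <- gen_thermograms(grid, reps = 3L, noise_sd = 0.02, seed = 11)
  expect_identical(g$thermograms, g2$thermograms)
})
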