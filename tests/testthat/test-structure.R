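# Structure parsing, contact chemistry, water bridges, readout map and
# methylation-sensitivity rules.

test_that("fixture write -> parse round-trips coordinates", {
  fx <- build_fixture(list(
    list(base = "A", base_atom = "N7", probe_res = "ASN",
         probe_atom = "ND2", distance = 2.9)))
  m <- parse_structure(fx$path)
  expect_s3_class(m, "structure_model")
  merged <- merge(fx$atoms, m$atoms, by = c("chain", "resno", "atom"))
  expect_equal(nrow(merged), nrow(fx$atoms))
  expect_true(all(abs(merged$x.x - merged$x.y) < 0.001))
  expect_true(all(abs(merged$y.x - merged$y.y) < 0.001))
  expect_true(all(abs(merged$z.x - merged$z.y) < 0.001))
  expect_setequal(unique(m$atoms$class), c("protein", "nucleic"))
})

test_that("parser flags malformed records and missing nucleic chains", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N7  DA B   1"), p)   # truncated record
  expect_error(parse_structure(p), "line 1")
  writeLines(sprintf(
    "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    "ATOM", 1L, " CA ", "GLY", "A", 1L, 0, 0, 0, 1, 0, "C"), p)
  expect_warning(parse_structure(p), "no nucleic")
})

test_that("idealized base templates have standard bond geometry", {
  std <- list(
    A = list(c("N9", "C8", 1.374), c("C8", "N7", 1.311), c("N7", "C5", 1.388),
             c("C5", "C6", 1.404), c("C6", "N6", 1.335), c("C6", "N1", 1.351),
             c("N1", "C2", 1.339), c("C2", "N3", 1.331), c("N3", "C4", 1.344),
             c("C4", "C5", 1.383), c("C4", "N9", 1.374)),
    G = list(c("C6", "O6", 1.237), c("C2", "N2", 1.341), c("N1", "C2", 1.373)),
    C = list(c("C2", "O2", 1.240), c("C4", "N4", 1.335), c("C4", "C5", 1.425),
             c("C5", "C6", 1.339)),
    T = list(c("C2", "O2", 1.220), c("C4", "O4", 1.228), c("C5", "C7", 1.499))
  )
  for (b in names(std)) {
    tpl <- base_template(b)
    for (bond in std[[b]]) {
      a1 <- tpl[tpl$atom == bond[1], ]
      a2 <- tpl[tpl$atom == bond[2], ]
      d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
      expect_lt(abs(d - as.numeric(bond[3])), 0.1,
                label = paste(b, bond[1], bond[2], "distance", round(d, 3)))
    }
  }
})

test_that("find_contacts detects planted hydrogen bonds and apolar pairs", {
  fx <- build_fixture(list(
    list(base = "A", base_atom = "N7", probe_res = "ASN",
         probe_atom = "ND2", distance = 2.90),
    list(base = "C", base_atom = "C5", probe_res = "LEU",
         probe_atom = "CD2", distance = 3.70,
         direction = c(0.570, -0.419, 0.707))))
  m <- parse_structure(fx$path)
  ct <- find_contacts(m)
  expect_equal(nrow(ct), 2L)
  hb <- ct[ct$kind == "direct-hbond", ]
  expect_equal(hb$distance, 2.90, tolerance = 1e-6)
  expect_equal(hb$dna_atom, "N7")
  expect_equal(hb$dna_class, "base")
  ap <- ct[ct$kind == "apolar-proximity", ]
  expect_equal(ap$distance, 3.70, tolerance = 1e-6)
  expect_equal(ap$protein_atom, "CD2")
})

test_that("reported distances equal recomputed Euclidean distances", {
  fx <- wer_interface_fixture()
  m <- parse_structure(fx$path)
  ct <- find_contacts(m)
  for (i in seq_len(nrow(ct))) {
    pa <- m$atoms[m$atoms$class == "protein" &
                    m$atoms$resno == ct$protein_resno[i] &
                    m$atoms$atom == ct$protein_atom[i], ]
    da <- m$atoms[m$atoms$class == "nucleic" &
                    m$atoms$resno == ct$dna_resno[i] &
                    m$atoms$atom == ct$dna_atom[i], ]
    d <- sqrt((pa$x - da$x)^2 + (pa$y - da$y)^2 + (pa$z - da$z)^2)
    expect_lt(abs(d - ct$distance[i]), 0.01)
  }
})

test_that("contacts match the all-pairs brute-force oracle", {
  fx <- wer_interface_fixture()
  m <- parse_structure(fx$path)
  for (cut in list(c(3.5, 4.5), c(3.0, 4.0), c(5.0, 6.0))) {
    a <- find_contacts(m, d_hb = cut[1], d_ap = cut[2])
    b <- bf_contacts(m, d_hb = cut[1], d_ap = cut[2])
    expect_identical(contact_key(a), contact_key(b),
                     label = paste("cutoffs", cut[1], cut[2]))
  }
})

test_that("enlarging cutoffs never removes a contact", {
  fx <- wer_interface_fixture()
  m <- parse_structure(fx$path)
  small <- find_contacts(m, d_hb = 3.0, d_ap = 3.8)
  big <- find_contacts(m, d_hb = 3.6, d_ap = 4.6)
  expect_true(all(contact_key(small) %in% contact_key(big)))
  expect_gte(nrow(big), nrow(small))
})

test_that("water bridges require both a protein and a DNA polar partner", {
  fx <- build_fixture(list(
    list(base = "T", base_atom = "O4", probe_res = "ASN",
         probe_atom = "OD1", distance = 2.8, water_bridge = TRUE)))
  m <- parse_structure(fx$path)
  wb <- find_water_bridges(m)
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$kind, "water-mediated")
  expect_equal(wb$distance, 2.8, tolerance = 1e-6)
  expect_equal(wb$d_protein_water, 2.8, tolerance = 1e-6)
  expect_match(wb$bridging_water, "^W:")
  # the protein atom sits 5.6 A from the base atom: no direct contact
  expect_equal(nrow(find_contacts(m)), 0L)

  # water near only the protein side: no bridge
  fx2 <- build_fixture(list(
    list(base = "T", base_atom = "O4", probe_res = "ASN",
         probe_atom = "OD1", distance = 4.0, water_bridge = TRUE,
         d_protein_water = 2.8)))
  expect_equal(nrow(find_water_bridges(parse_structure(fx2$path))), 0L)

  # two waters bridging the same pair yield two records
  fx3 <- build_fixture(list(
    list(base = "T", base_id = "t", base_atom = "O4", probe_res = "ASN",
         probe_atom = "OD1", distance = 2.8, water_bridge = TRUE)))
  atoms <- fx3$atoms
  w2 <- atoms[atoms$resid == "HOH", ]
  w2$resno <- 2L
  w2$x <- w2$x + 0.3
  mybdna:::write_pdb_atoms(rbind(atoms, w2), fx3$path)
  expect_equal(nrow(find_water_bridges(parse_structure(fx3$path))), 2L)
})

test_that("readout_map separates base-specific from backbone-only residues", {
  fx <- wer_interface_fixture()
  m <- parse_structure(fx$path)
  ct <- find_contacts(m)
  rm <- readout_map(ct, helices = list(H3 = c(1L, 10L)))
  expect_equal(nrow(rm$residues), 5L)
  expect_true(all(rm$residues$readout == "base-specific"))
  expect_true(length(rm$helices$H3) > 0)

  # phosphate-only contact set: backbone-only labels
  bb <- ct[1, ]
  bb$dna_atom <- "OP1"
  bb$dna_class <- "phosphate"
  rm2 <- readout_map(bb)
  expect_equal(rm2$residues$readout, "backbone-only")

  rm3 <- readout_map(ct[0, ])
  expect_equal(nrow(rm3$residues), 0L)
})

test_that("5mC rule fires on the packed Leu-C5 geometry only", {
  fx <- build_fixture(list(
    list(base = "C", base_atom = "C5", probe_res = "LEU",
         probe_atom = "CD2", distance = 3.70,
         direction = c(0.570, -0.419, 0.707))))
  m <- parse_structure(fx$path)
  ct <- find_contacts(m)
  sens <- predict_methyl_sensitivity(m, ct)
  expect_equal(nrow(sens), 1L)
  expect_equal(sens$modification, "5mC")
  expect_equal(sens$mechanism, "steric-clash")

  # same probe at 4.6 A: no apolar contact at all, no flag
  fx2 <- build_fixture(list(
    list(base = "C", base_atom = "C5", probe_res = "LEU",
         probe_atom = "CD2", distance = 4.60,
         direction = c(0.570, -0.419, 0.707))))
  m2 <- parse_structure(fx2$path)
  expect_equal(nrow(predict_methyl_sensitivity(m2, find_contacts(m2))), 0L)
})

test_that("6mA rule requires N6 to donate; N7-only adenines are not flagged", {
  fx <- build_fixture(list(
    list(base = "A", base_atom = "N6", probe_res = "ASN",
         probe_atom = "OD1", distance = 3.0)))
  m <- parse_structure(fx$path)
  sens <- predict_methyl_sensitivity(m, find_contacts(m))
  expect_equal(sens$modification, "6mA")
  expect_equal(sens$mechanism, "donor-occlusion")

  fx2 <- build_fixture(list(
    list(base = "A", base_atom = "N7", probe_res = "ASN",
         probe_atom = "ND2", distance = 2.9)))
  m2 <- parse_structure(fx2$path)
  expect_equal(nrow(predict_methyl_sensitivity(m2, find_contacts(m2))), 0L)
})

test_that("altloc policy keeps the first conformer", {
  p <- tempfile(fileext = ".pdb")
  altline <- function(serial, alt, x) sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    "ATOM", serial, " N7 ", alt, "DA", "B", 1L, x, 0, 0, 0.5, 0, "N")
  writeLines(c(altline(1L, "A", 0), altline(2L, "B", 9), "END"), p)
  m <- suppressWarnings(parse_structure(p))
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 0)
})
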