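# Synthetic protein-DNA interface fixtures: idealized planar nucleobases
# with probe side-chain atoms placed at exact distances, written as
# PDB-format files with the intended (planted) contact list recorded as
# ground truth.

# Idealized planar base-atom coordinates (Angstrom) in the standard base
# reference frame; all intra-base bond lengths agree with standard values to
# well within 0.1 A.  z = 0 is the base plane.
BASE_TEMPLATES <- list(
  A = data.frame(
    atom = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    x = c(-2.479, -1.291, 0.024, 0.877, 0.071, 0.369, 1.611, -0.668, -1.912,
          -2.320, -1.267),
    y = c(5.346, 4.498, 4.897, 3.902, 2.771, 1.398, 0.909, 0.532, 1.023,
          2.290, 3.124),
    z = 0, stringsAsFactors = FALSE),
  G = data.frame(
    atom = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
             "N3", "C4"),
    x = c(-2.477, -1.289, 0.023, 0.870, 0.071, 0.424, 1.554, -0.700, -1.999,
          -2.949, -2.342, -1.265),
    y = c(5.399, 4.551, 4.962, 3.969, 2.833, 1.460, 0.955, 0.641, 1.087,
          0.139, 2.364, 3.177),
    z = 0, stringsAsFactors = FALSE),
  C = data.frame(
    atom = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    x = c(-2.477, -1.285, -1.472, -2.628, -0.391, 0.837, 1.875, 1.056,
          -0.023),
    y = c(5.402, 4.542, 3.158, 2.709, 2.344, 2.868, 2.027, 4.275, 5.068),
    z = 0, stringsAsFactors = FALSE),
  T = data.frame(
    atom = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    x = c(-2.481, -1.284, -1.462, -2.562, -0.298, 0.994, 1.944, 1.106,
          2.466, -0.024),
    y = c(5.354, 4.500, 3.135, 2.608, 2.407, 2.897, 2.119, 4.338, 4.961,
          5.057),
    z = 0, stringsAsFactors = FALSE)
)

#' Idealized base template coordinates
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return `data.frame` with columns `atom`, `x`, `y`, `z`.
#' @export
base_template <- function(base) {
  base <- toupper(base)
  if (!base %in% names(BASE_TEMPLATES)) stop("no template for base ", base)
  BASE_TEMPLATES[[base]]
}

#' Build a synthetic protein-DNA interface fixture
#'
#' Each placement positions one idealized nucleobase (translated to its own
#' site unless a `base_id` is shared) and one probe atom of a named protein
#' residue at an exact distance from a chosen base atom, along `direction`
#' (default: the base-plane normal, which keeps the probe clear of
#' neighbouring base atoms).  `water_bridge` placements insert a water oxygen
#' between the base atom and the probe atom instead.
#'
#' A placement is a list with fields:
#' \describe{
#'   \item{base, base_atom}{target nucleobase (`"A"/"C"/"G"/"T"`) and atom.}
#'   \item{probe_res, probe_atom}{protein residue name (3-letter) and atom.}
#'   \item{distance}{probe to base-atom distance in Angstrom.}
#'   \item{base_id}{optional label; placements sharing it target one base
#'     copy.}
#'   \item{direction}{optional length-3 vector for the probe offset.}
#'   \item{water_bridge}{if `TRUE`, place a water between base atom and
#'     probe: water at `distance` from the base atom, probe at
#'     `d_protein_water` (default `distance`) beyond the water.}
#' }
#'
#' @param placements List of placement lists (see Details).
#' @param path Optional output PDB path; when `NULL` a tempfile is used.
#' @return List of class `"structure_fixture"`: `$path`, `$atoms`, `$truth`
#'   (planted contact table with expected kinds and distances).
#' @export
build_fixture <- function(placements, path = NULL) {
  path <- path %||% tempfile(fileext = ".pdb")
  atoms <- list()
  truth <- list()
  base_sites <- list()    # base_id -> list(resno, offset, template, resid)
  dna_resno <- 0L
  prot_resno <- 0L
  wat_resno <- 0L
  site_spacing <- 20      # A between independent base sites

  add_atom <- function(chain, resno, resid, atom, xyz, het = FALSE) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, atom = atom,
      element = element_of(atom), x = xyz[1L], y = xyz[2L], z = xyz[3L],
      occ = 1, het = het, stringsAsFactors = FALSE)
  }

  for (pl in placements) {
    base <- toupper(pl$base)
    bid <- pl$base_id %||% paste0("site", length(base_sites) + 1L)
    if (is.null(base_sites[[bid]])) {
      dna_resno <- dna_resno + 1L
      off <- c((length(base_sites)) * site_spacing, 0, 0)
      tpl <- base_template(base)
      base_sites[[bid]] <- list(resno = dna_resno, offset = off,
                                template = tpl, resid = paste0("D", base))
      for (k in seq_len(nrow(tpl)))
        add_atom("B", dna_resno, paste0("D", base), tpl$atom[k],
                 c(tpl$x[k] + off[1L], tpl$y[k] + off[2L], tpl$z[k] + off[3L]))
    }
    site <- base_sites[[bid]]
    if (site$resid != paste0("D", base))
      stop("base_id '", bid, "' reused with a different base")
    trow <- site$template[site$template$atom == pl$base_atom, , drop = FALSE]
    if (nrow(trow) != 1L)
      stop("base ", base, " has no atom ", pl$base_atom)
    target <- c(trow$x, trow$y, trow$z) + site$offset
    dir <- pl$direction %||% c(0, 0, 1)
    dir <- dir / sqrt(sum(dir^2))
    prot_resno <- prot_resno + 1L
    if (isTRUE(pl$water_bridge)) {
      d1 <- pl$distance
      d2 <- pl$d_protein_water %||% pl$distance
      wxyz <- target + d1 * dir
      pxyz <- wxyz + d2 * dir
      wat_resno <- wat_resno + 1L
      add_atom("W", wat_resno, "HOH", "O", wxyz, het = TRUE)
      add_atom("A", prot_resno, toupper(pl$probe_res), pl$probe_atom, pxyz)
      truth[[length(truth) + 1L]] <- data.frame(
        protein_res = toupper(pl$probe_res), protein_resno = prot_resno,
        protein_atom = pl$probe_atom, dna_res = site$resid,
        dna_resno = site$resno, dna_atom = pl$base_atom,
        distance = d1, kind = "water-mediated",
        bridging_water = paste0("W:", wat_resno), stringsAsFactors = FALSE)
    } else {
      pxyz <- target + pl$distance * dir
      add_atom("A", prot_resno, toupper(pl$probe_res), pl$probe_atom, pxyz)
      kind <- if (element_of(pl$probe_atom) %in% c("C", "S"))
        "apolar-proximity" else "direct-hbond"
      truth[[length(truth) + 1L]] <- data.frame(
        protein_res = toupper(pl$probe_res), protein_resno = prot_resno,
        protein_atom = pl$probe_atom, dna_res = site$resid,
        dna_resno = site$resno, dna_atom = pl$base_atom,
        distance = pl$distance, kind = kind,
        bridging_water = NA_character_, stringsAsFactors = FALSE)
    }
  }
  atoms <- if (length(atoms)) do.call(rbind, atoms) else
    data.frame(chain = character(), resno = integer(), resid = character(),
               atom = character(), element = character(), x = numeric(),
               y = numeric(), z = numeric(), occ = numeric(),
               het = logical(), stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  write_pdb_atoms(atoms, path)
  structure(list(path = path, atoms = atoms, truth = truth),
            class = "structure_fixture")
}

# Minimal fixed-width PDB ATOM/HETATM writer for fixture output.
write_pdb_atoms <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(atoms))) {
    name <- atoms$atom[i]
    name_field <- if (nchar(name) >= 4L) substr(name, 1L, 4L)
      else sprintf(" %-3s", name)
    writeLines(sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (atoms$het[i]) "HETATM" else "ATOM", i, name_field,
      atoms$resid[i], atoms$chain[i], atoms$resno[i],
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$occ[i], 0,
      atoms$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Composite WER-like interface fixture
#'
#' Builds the five-base fixture mirroring the published readout geometry of
#' the WER-DNA interface: Asn carboxamide pairs reading the N7/N6 edge of
#' both adenines of the AAC core (2.9/3.0 Angstrom), a Leu methyl packed
#' against the cytosine C5 (3.7 Angstrom), and Lys ammonium groups on the O6
#' of the two guanines read in the complementary/downstream positions (2.9
#' and 2.7 Angstrom).
#'
#' @param path Optional output PDB path.
#' @return A `"structure_fixture"` (see [build_fixture()]).
#' @export
wer_interface_fixture <- function(path = NULL) {
  # Leu probe direction: tilted away from the cytosine C6/N4 neighbourhood so
  # the only in-range apolar pair is the intended C5 contact.
  leu_dir <- c(0.570, -0.419, 0.707)
  build_fixture(list(
    list(base = "A", base_id = "A10", base_atom = "N7",
         probe_res = "ASN", probe_atom = "ND2", distance = 2.9),
    list(base = "A", base_id = "A10", base_atom = "N6",
         probe_res = "ASN", probe_atom = "OD1", distance = 3.0),
    list(base = "A", base_id = "A11", base_atom = "N7",
         probe_res = "ASN", probe_atom = "ND2", distance = 2.9),
    list(base = "A", base_id = "A11", base_atom = "N6",
         probe_res = "ASN", probe_atom = "OD1", distance = 3.0),
    list(base = "C", base_id = "C12", base_atom = "C5",
         probe_res = "LEU", probe_atom = "CD2", distance = 3.7,
         direction = leu_dir),
    list(base = "G", base_id = "G11s", base_atom = "O6",
         probe_res = "LYS", probe_atom = "NZ", distance = 2.9),
    list(base = "G", base_id = "G14", base_atom = "O6",
         probe_res = "LYS", probe_atom = "NZ", distance = 2.7)
  ), path = path)
}
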