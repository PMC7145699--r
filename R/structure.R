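# Protein-DNA interface analysis from atomic coordinates: parsing, direct
# and water-mediated hydrogen bonds, apolar proximities, per-residue readout
# classification, and methylation-sensitivity rules.

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records (via bio3d), resolves alternate locations by
#' keeping the first conformer (blank or `A`), and classifies atoms by
#' residue content into protein / nucleic / water / other.
#'
#' @param path Path to a PDB-format file.
#' @return List of class `"structure_model"` with `$atoms` (`data.frame`:
#'   `chain`, `resno`, `resid`, `atom`, `element`, `x`, `y`, `z`, `occ`,
#'   `class`) and `$path`.
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  for (i in rec) {
    if (nchar(lines[i]) < 54)
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": fewer than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)) || any(!is.finite(xyz)))
      stop("malformed coordinates at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[alt_ok, , drop = FALSE]
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    resid = toupper(at$resid),
    atom  = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     element_of(at$elety), trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!duplicated(atoms[c("chain", "resno", "atom")]), ,
                 drop = FALSE]
  atoms$class <- classify_residue(atoms$resid)
  if (!any(atoms$class == "nucleic"))
    warning("no nucleic-acid chain found in ", path,
            "; protein-DNA contacts will be empty")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cls <- table(x$atoms$class)
  cat("structure_model:", nrow(x$atoms), "atoms (",
      paste(names(cls), as.integer(cls), collapse = ", "), ")\n")
  invisible(x)
}

# Attach chemistry roles to an atom table; nucleotide residues look up both
# "DA"-style and bare names via the table (which carries both).
.with_roles <- function(atoms) {
  key <- paste(CHEMISTRY_TABLE$res, CHEMISTRY_TABLE$atom, sep = "|")
  idx <- match(paste(atoms$resid, atoms$atom, sep = "|"), key)
  atoms$role <- ifelse(is.na(idx), "none", CHEMISTRY_TABLE$role[idx])
  atoms
}

.polar <- function(role) role %in% c("donor", "acceptor", "both")

empty_contacts <- function() {
  data.frame(protein_chain = character(), protein_resno = integer(),
             protein_res = character(), protein_atom = character(),
             dna_chain = character(), dna_resno = integer(),
             dna_res = character(), dna_atom = character(),
             distance = numeric(), kind = character(),
             dna_class = character(), bridging_water = character(),
             stringsAsFactors = FALSE)
}

#' Find direct protein-DNA contacts
#'
#' Reports every donor/acceptor-complementary protein-DNA atom pair within
#' `d_hb` as a direct hydrogen bond, and every protein apolar carbon/sulfur
#' within `d_ap` of an exposed DNA base carbon as an apolar proximity.  No
#' angle criterion is applied: crystal models carry no hydrogens, so the
#' screen is distance-plus-chemistry only.
#'
#' @param model A `"structure_model"` from [parse_structure()].
#' @param d_hb Hydrogen-bond distance cutoff in Angstrom (default 3.5).
#' @param d_ap Apolar-proximity cutoff in Angstrom (default 4.5).
#' @return `data.frame` of contact records: protein and DNA atom identifiers,
#'   `distance`, `kind` (`direct-hbond` / `apolar-proximity`), `dna_class`
#'   (`base` / `phosphate` / `sugar`), `bridging_water` (`NA` here).
#' @export
find_contacts <- function(model, d_hb = 3.5, d_ap = 4.5) {
  atoms <- .with_roles(model$atoms)
  unknown <- unique(atoms$resid[atoms$class == "other"])
  if (length(unknown))
    warning("unknown residue(s) skipped: ", paste(unknown, collapse = ", "))
  prot <- atoms[atoms$class == "protein", , drop = FALSE]
  dna  <- atoms[atoms$class == "nucleic", , drop = FALSE]
  if (!nrow(prot) || !nrow(dna)) return(empty_contacts())
  dmat <- cross_dist(prot, dna)
  cand <- which(dmat <= max(d_hb, d_ap), arr.ind = TRUE)
  if (!nrow(cand)) return(empty_contacts())
  p <- prot[cand[, 1L], ]
  d <- dna[cand[, 2L], ]
  dist <- dmat[cand]
  hb <- ((.polar(p$role) & p$role != "acceptor" & .polar(d$role) &
            d$role != "donor") |
         (.polar(p$role) & p$role != "donor" & .polar(d$role) &
            d$role != "acceptor")) & dist <= d_hb
  ap <- p$role == "apolar" & d$role == "apolar" & dist <= d_ap
  keep <- hb | ap
  if (!any(keep)) return(empty_contacts())
  out <- data.frame(
    protein_chain = p$chain[keep], protein_resno = p$resno[keep],
    protein_res = p$resid[keep], protein_atom = p$atom[keep],
    dna_chain = d$chain[keep], dna_resno = d$resno[keep],
    dna_res = d$resid[keep], dna_atom = d$atom[keep],
    distance = round(dist[keep], 3L),
    kind = ifelse(hb[keep], "direct-hbond", "apolar-proximity"),
    dna_class = dna_atom_class(d$atom[keep]),
    bridging_water = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$dna_chain, out$dna_resno, out$protein_resno,
                   out$protein_atom, out$dna_atom), ]
  rownames(out) <- NULL
  out
}

cross_dist <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * tcrossprod(am, bm)
  sqrt(pmax(d2, 0))
}

#' Find water-mediated protein-DNA bridges
#'
#' A water oxygen within `d_hb` of at least one polar protein atom and one
#' polar DNA atom yields one record per (protein atom, water, DNA atom)
#' triple.  Donor/acceptor complementarity is not enforced through the water
#' (water is both).
#'
#' @inheritParams find_contacts
#' @return Contact records with `kind == "water-mediated"`; `distance` is the
#'   water-DNA leg, and `d_protein_water` holds the protein-water leg.
#' @export
find_water_bridges <- function(model, d_hb = 3.5) {
  atoms <- .with_roles(model$atoms)
  wat <- atoms[atoms$class == "water" & atoms$atom == "O", , drop = FALSE]
  prot <- atoms[atoms$class == "protein" & .polar(atoms$role), , drop = FALSE]
  dna <- atoms[atoms$class == "nucleic" & .polar(atoms$role), , drop = FALSE]
  out <- empty_contacts()
  out$d_protein_water <- numeric(0)
  if (!nrow(wat) || !nrow(prot) || !nrow(dna)) return(out)
  dp <- cross_dist(wat, prot)
  dd <- cross_dist(wat, dna)
  rows <- list()
  for (w in seq_len(nrow(wat))) {
    pi <- which(dp[w, ] <= d_hb)
    di <- which(dd[w, ] <= d_hb)
    if (!length(pi) || !length(di)) next
    for (i in pi) for (j in di) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_chain = prot$chain[i], protein_resno = prot$resno[i],
        protein_res = prot$resid[i], protein_atom = prot$atom[i],
        dna_chain = dna$chain[j], dna_resno = dna$resno[j],
        dna_res = dna$resid[j], dna_atom = dna$atom[j],
        distance = round(dd[w, j], 3L),
        kind = "water-mediated",
        dna_class = dna_atom_class(dna$atom[j]),
        bridging_water = paste0(wat$chain[w], ":", wat$resno[w]),
        d_protein_water = round(dp[w, i], 3L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize contacts per DNA residue and per recognition helix
#'
#' Classifies each contacted DNA residue as base-specific (at least one
#' base-class contact) or backbone-only, and lists the protein residues
#' making base-specific contacts from each recognition helix.  Default helix
#' ranges are the two major-groove helices of the WER R2R3 domain, H3
#' (residues 54-65) and H6 (residues 105-116).
#'
#' @param contacts Contact records (direct, apolar and/or water-mediated
#'   rows may be concatenated).
#' @param helices Named list of `c(first, last)` protein residue numbers.
#' @return List of class `"readout_map"`: `$residues` (per-DNA-residue
#'   `data.frame` with contact counts and `readout` label) and `$helices`
#'   (per-helix character vectors `RES-resno` of base-contacting residues).
#' @export
readout_map <- function(contacts,
                        helices = list(H3 = c(54L, 65L), H6 = c(105L, 116L))) {
  if (!nrow(contacts)) {
    return(structure(list(
      residues = data.frame(dna_chain = character(), dna_resno = integer(),
                            dna_res = character(), n_base = integer(),
                            n_backbone = integer(), readout = character(),
                            stringsAsFactors = FALSE),
      helices = lapply(helices, function(h) character())),
      class = "readout_map"))
  }
  key <- paste(contacts$dna_chain, contacts$dna_resno, contacts$dna_res,
               sep = "|")
  is_base <- contacts$dna_class == "base"
  res <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    data.frame(dna_chain = contacts$dna_chain[i[1L]],
               dna_resno = contacts$dna_resno[i[1L]],
               dna_res = contacts$dna_res[i[1L]],
               n_base = sum(is_base[i]),
               n_backbone = sum(!is_base[i]),
               stringsAsFactors = FALSE)
  }))
  res$readout <- ifelse(res$n_base > 0L, "base-specific", "backbone-only")
  res <- res[order(res$dna_chain, res$dna_resno), ]
  rownames(res) <- NULL
  hx <- lapply(helices, function(h) {
    i <- is_base & contacts$protein_resno >= h[1L] &
      contacts$protein_resno <= h[2L]
    sort(unique(paste0(contacts$protein_res[i], "-",
                       contacts$protein_resno[i])))
  })
  structure(list(residues = res, helices = hx), class = "readout_map")
}

#' @export
print.readout_map <- function(x, ...) {
  cat("Readout map:", nrow(x$residues), "contacted DNA residue(s)\n")
  if (nrow(x$residues)) print(x$residues)
  for (h in names(x$helices))
    cat(sprintf("  %s base-readout residues: %s\n", h,
                if (length(x$helices[[h]]))
                  paste(x$helices[[h]], collapse = ", ") else "(none)"))
  invisible(x)
}

#' Predict 5mC/6mA methylation sensitivity of a bound DNA site
#'
#' Applies two geometric rules to a protein-DNA complex:
#'
#' * **5mC steric clash** - for every cytosine with at least one base-class
#'   contact, a virtual 5-methyl carbon is placed in the base plane along the
#'   C4->C5 exocyclic direction, `methyl_bond` Angstrom from C5.  The site is
#'   flagged when any protein atom comes closer to the virtual methyl than
#'   the sum of van der Waals radii minus `clash_tol`, or when an
#'   apolar-proximity contact to C5 itself exists at <= 4.0 Angstrom (a
#'   packed hydrophobic probe on the 5 position, as for a Leu side chain
#'   against the cytosine ring).
#' * **6mA donor occlusion** - every adenine whose N6 amino group donates at
#'   least one direct base hydrogen bond is flagged: N6 methylation
#'   compromises that donation.
#'
#' @param model The `"structure_model"` the contacts were computed from.
#' @param contacts Output of [find_contacts()].
#' @param clash_tol Steric tolerance subtracted from the vdW sum (default
#'   0.4 Angstrom).
#' @param methyl_bond C5-methyl bond length used for the virtual methyl
#'   (default 1.50 Angstrom).
#' @return `data.frame` of flagged sites: `dna_chain`, `dna_resno`,
#'   `dna_res`, `modification` (`5mC`/`6mA`), `mechanism` (`steric-clash` /
#'   `donor-occlusion`), `evidence`, `min_gap` (signed clearance for steric
#'   flags, `NA` otherwise).
#' @export
predict_methyl_sensitivity <- function(model, contacts, clash_tol = 0.4,
                                       methyl_bond = 1.50) {
  atoms <- model$atoms
  sites <- list()
  base_contacts <- contacts[contacts$dna_class == "base", , drop = FALSE]

  # --- 5mC rule over contacted cytosines ---
  cyt <- unique(base_contacts[base_contacts$dna_res %in% c("C", "DC"),
                              c("dna_chain", "dna_resno", "dna_res")])
  prot <- atoms[atoms$class == "protein", , drop = FALSE]
  if (nrow(cyt) && nrow(prot)) {
    pr <- VDW_RADII[prot$element]
    pr[is.na(pr)] <- VDW_RADII[["C"]]
    for (i in seq_len(nrow(cyt))) {
      res_at <- atoms[atoms$chain == cyt$dna_chain[i] &
                        atoms$resno == cyt$dna_resno[i], , drop = FALSE]
      c4 <- res_at[res_at$atom == "C4", c("x", "y", "z")]
      c5 <- res_at[res_at$atom == "C5", c("x", "y", "z")]
      clash <- FALSE; gap <- NA_real_; ev <- character()
      if (nrow(c4) == 1L && nrow(c5) == 1L) {
        v <- as.numeric(c5) - as.numeric(c4)
        vm <- as.numeric(c5) + methyl_bond * v / sqrt(sum(v^2))
        dd <- sqrt((prot$x - vm[1L])^2 + (prot$y - vm[2L])^2 +
                     (prot$z - vm[3L])^2)
        lim <- VDW_RADII[["C"]] + pr - clash_tol
        gap <- min(dd - lim)
        if (any(dd < lim)) {
          clash <- TRUE
          j <- which.min(dd - lim)
          ev <- sprintf("virtual 5-methyl %.2f A from %s-%d %s (limit %.2f)",
                        dd[j], prot$resid[j], prot$resno[j], prot$atom[j],
                        lim[j])
        }
      }
      apc <- contacts$kind == "apolar-proximity" &
        contacts$dna_chain == cyt$dna_chain[i] &
        contacts$dna_resno == cyt$dna_resno[i] &
        contacts$dna_atom == "C5" & contacts$distance <= 4.0
      if (any(apc)) {
        clash <- TRUE
        k <- which(apc)[1L]
        ev <- c(ev, sprintf("apolar contact %s-%d %s to C5 at %.2f A",
                            contacts$protein_res[k],
                            contacts$protein_resno[k],
                            contacts$protein_atom[k], contacts$distance[k]))
      }
      if (clash)
        sites[[length(sites) + 1L]] <- data.frame(
          dna_chain = cyt$dna_chain[i], dna_resno = cyt$dna_resno[i],
          dna_res = cyt$dna_res[i], modification = "5mC",
          mechanism = "steric-clash",
          evidence = paste(ev, collapse = "; "), min_gap = round(gap, 3L),
          stringsAsFactors = FALSE)
    }
  }

  # --- 6mA rule: N6 engaged as donor in a direct base H-bond ---
  n6 <- base_contacts[base_contacts$kind == "direct-hbond" &
                        base_contacts$dna_atom == "N6" &
                        base_contacts$dna_res %in% c("A", "DA"), ,
                      drop = FALSE]
  if (nrow(n6)) {
    ukey <- !duplicated(n6[c("dna_chain", "dna_resno")])
    for (i in which(ukey)) {
      all_i <- n6$dna_chain == n6$dna_chain[i] & n6$dna_resno == n6$dna_resno[i]
      ev <- sprintf("N6 donates to %s-%d %s (%.2f A)",
                    n6$protein_res[all_i], n6$protein_resno[all_i],
                    n6$protein_atom[all_i], n6$distance[all_i])
      sites[[length(sites) + 1L]] <- data.frame(
        dna_chain = n6$dna_chain[i], dna_resno = n6$dna_resno[i],
        dna_res = n6$dna_res[i], modification = "6mA",
        mechanism = "donor-occlusion",
        evidence = paste(ev, collapse = "; "), min_gap = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(dna_chain = character(), dna_resno = integer(),
               dna_res = character(), modification = character(),
               mechanism = character(), evidence = character(),
               min_gap = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
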