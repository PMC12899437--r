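#' Glycosidic linkage specification
#'
#' Identifies one glycosidic linkage: the donor residue i contributes
#' O5_i and the anomeric C1_i; the acceptor residue i-1 contributes the
#' attachment carbon CX (X = 3 for a 1-3 linkage, 4 for a 1-4 linkage)
#' and C(X-1). The bridging oxygen conventionally belongs to the
#' acceptor residue but is located geometrically, not by bookkeeping.
#'
#' @param donor_residue_id,acceptor_residue_id residue numbers.
#' @param X attachment carbon number, 3 or 4.
#' @return object of class `linkage_spec`.
#' @export
linkage_spec <- function(donor_residue_id, acceptor_residue_id, X) {
  if (!X %in% c(3, 4)) stop("linkage_spec: X must be 3 or 4")
  if (donor_residue_id == acceptor_residue_id)
    stop("linkage_spec: donor and acceptor must differ")
  structure(list(donor_residue_id = donor_residue_id,
                 acceptor_residue_id = acceptor_residue_id,
                 X = as.integer(X)),
            class = "linkage_spec")
}

get_atom_xyz <- function(atoms, residue, name, what) {
  i <- which(atoms$residue_number == residue &
             toupper(atoms$name) == toupper(name))
  if (length(i) == 0)
    stop(sprintf("phi_psi: atom %s of residue %d (%s) not found",
                 name, residue, what))
  c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
}

#' Glycosidic (phi, psi) of a linkage
#'
#' IUPAC heavy-atom definitions:
#' phi = O5_i - C1_i - OX_{i-1} - CX_{i-1} and
#' psi = C1_i - OX_{i-1} - CX_{i-1} - C(X-1)_{i-1}. The bridging oxygen
#' is resolved by a covalent-distance search (an O within `cutoff` of
#' both C1_i and CX_{i-1}), since residue assignment of the bridge
#' differs between PDB dialects. With `convention = "nmr"`, H1_i
#' replaces O5_i and HX_{i-1} replaces C(X-1)_{i-1}, the proton-based
#' definition used in NMR work; those hydrogens must then be present.
#'
#' @param structure a [structure_model()].
#' @param spec a [linkage_spec()].
#' @param convention "iupac" (default) or "nmr".
#' @param cutoff covalent C-O distance cutoff for the bridge search,
#'   Angstrom.
#' @return list with `phi`, `psi` (degrees, wrapped to (-180, 180]).
#' @export
phi_psi <- function(structure, spec, convention = c("iupac", "nmr"),
                    cutoff = 1.7) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "linkage_spec"))
  at <- structure$atoms
  X <- spec$X
  c1 <- get_atom_xyz(at, spec$donor_residue_id, "C1", "donor")
  cx <- get_atom_xyz(at, spec$acceptor_residue_id, paste0("C", X),
                     "acceptor")
  ## bridging oxygen: bonded to both anomeric and attachment carbons
  ox_cand <- which(startsWith(toupper(at$name), "O"))
  d1 <- sqrt((at$x[ox_cand] - c1[1])^2 + (at$y[ox_cand] - c1[2])^2 +
             (at$z[ox_cand] - c1[3])^2)
  d2 <- sqrt((at$x[ox_cand] - cx[1])^2 + (at$y[ox_cand] - cx[2])^2 +
             (at$z[ox_cand] - cx[3])^2)
  hit <- ox_cand[d1 <= cutoff & d2 <= cutoff]
  if (length(hit) == 0)
    stop(sprintf(
      "phi_psi: no bridging oxygen bonded to both C1 of residue %d and C%d of residue %d",
      spec$donor_residue_id, X, spec$acceptor_residue_id))
  ox <- c(at$x[hit[1]], at$y[hit[1]], at$z[hit[1]])
  if (convention == "iupac") {
    first <- get_atom_xyz(at, spec$donor_residue_id, "O5", "donor")
    last <- get_atom_xyz(at, spec$acceptor_residue_id, paste0("C", X - 1),
                         "acceptor")
  } else {
    first <- get_atom_xyz(at, spec$donor_residue_id, "H1", "donor")
    last <- get_atom_xyz(at, spec$acceptor_residue_id, paste0("H", X),
                         "acceptor")
  }
  list(phi = dihedral(first, c1, ox, cx),
       psi = dihedral(c1, ox, cx, last))
}

#' (phi, psi) table for all linkages of a model
#'
#' @param model a [structure_model()].
#' @param convention torsion convention, see [phi_psi()].
#' @return data.frame: donor, acceptor, X, phi, psi.
#' @export
linkage_table <- function(model, convention = "iupac") {
  links <- find_glycosidic_linkages(model)
  if (nrow(links) == 0)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      X = integer(0), phi = numeric(0), psi = numeric(0)))
  rows <- lapply(seq_len(nrow(links)), function(k) {
    tp <- phi_psi(model, linkage_spec(links$donor_residue_id[k],
                                      links$acceptor_residue_id[k],
                                      links$X[k]),
                  convention = convention)
    data.frame(donor = links$donor_residue_id[k],
               acceptor = links$acceptor_residue_id[k], X = links$X[k],
               phi = tp$phi, psi = tp$psi)
  })
  do.call(rbind, rows)
}
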