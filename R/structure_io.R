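#' Structure model
#'
#' One coordinate model of a (multi-model) structure: an atom table
#' with serials, names, residue assignment and coordinates.
#'
#' @param atoms data.frame with columns serial, name, residue_name,
#'   chain, residue_number, x, y, z.
#' @param model_id integer model identifier.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("serial", "name", "residue_name", "chain", "residue_number",
            "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("structure_model: atoms must have columns ",
         paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("structure_model: non-finite coordinates")
  key <- paste(atoms$chain, atoms$residue_number, atoms$name)
  if (anyDuplicated(key))
    stop("structure_model: duplicate (chain, residue, atom name): ",
         key[anyDuplicated(key)])
  structure(list(model_id = as.integer(model_id),
                 atoms = as.data.frame(atoms)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model %d: %d atoms, %d residues\n", x$model_id,
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$residue_number)))))
  invisible(x)
}

## atom-name synonym table for legacy carbohydrate PDB dialects; extend as
## new dialects are met. Lookup is case-insensitive and strips primes/stars.
RING_ATOM_SYNONYMS <- list(
  O5 = c("O5", "O5'", "O5*", "O"), C1 = c("C1", "C1'"),
  C2 = c("C2", "C2'"), C3 = c("C3", "C3'"), C4 = c("C4", "C4'"),
  C5 = c("C5", "C5'"))

resolve_ring_atom <- function(names_present, canonical) {
  syn <- toupper(RING_ATOM_SYNONYMS[[canonical]])
  hit <- which(toupper(names_present) %in% syn)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' Read a (multi-model) PDB file
#'
#' Parses fixed-column ATOM/HETATM records via bio3d, one
#' `structure_model` per MODEL block (a file without MODEL records
#' yields one implicit model). Records are pre-validated so that
#' malformed lines are reported with their line number.
#'
#' @param path PDB file.
#' @return list of [structure_model()] objects.
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (k in which(rec)) {
    ln <- lines[k]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop(sprintf("read_pdb_models: malformed %s record at line %d",
                   substr(ln, 1, 6), k))
  }
  if (!any(rec)) stop("read_pdb_models: no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  base <- data.frame(serial = at$eleno, name = at$elety,
                     residue_name = at$resid,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     residue_number = at$resno,
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    structure_model(cbind(base, x = co[, 1], y = co[, 2], z = co[, 3]),
                    model_id = m)
  })
}

#' Write structure models as a (multi-model) PDB file
#'
#' Record formatting is delegated to bio3d; multiple models are wrapped
#' in MODEL/ENDMDL blocks.
#'
#' @param models a `structure_model` or list of them.
#' @param path output file.
#' @param het write records as HETATM (default, carbohydrate convention).
#' @export
write_pdb_models <- function(models, path, het = TRUE) {
  if (inherits(models, "structure_model")) models <- list(models)
  out <- character(0)
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    at <- models[[m]]$atoms
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = rep(if (het) "HETATM" else "ATOM", nrow(at)),
                     resno = at$residue_number, resid = at$residue_name,
                     eleno = at$serial, elety = at$name, chain = at$chain,
                     end = FALSE)
    recs <- readLines(tmp)
    unlink(tmp)
    recs <- recs[grepl("^(ATOM  |HETATM|TER)", recs)]
    if (multi) recs <- c(sprintf("MODEL     %4d", m), recs, "ENDMDL")
    out <- c(out, recs)
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

## all oxygens within `cutoff` of a point
atoms_within <- function(atoms, point, cutoff, element_prefix = NULL) {
  d <- sqrt((atoms$x - point[1])^2 + (atoms$y - point[2])^2 +
            (atoms$z - point[3])^2)
  sel <- d <= cutoff
  if (!is.null(element_prefix))
    sel <- sel & startsWith(toupper(atoms$name), element_prefix)
  which(sel)
}

#' Discover glycosidic linkages in a model
#'
#' Distance-based: every inter-residue C1-O-C bridge within the
#' covalent C/O cutoff becomes a linkage, with the attachment carbon
#' number X read from the acceptor carbon name (C3 or C4). Ambiguous
#' connectivity (a bridging oxygen touching several candidate carbons)
#' is reported via warnings, never silently dropped.
#'
#' @param model a [structure_model()].
#' @param cutoff covalent C-O bond cutoff, Angstrom.
#' @return data.frame of [linkage_spec()] fields: donor_residue_id,
#'   acceptor_residue_id, X (0 rows when the model has no linkage).
#' @export
find_glycosidic_linkages <- function(model, cutoff = 1.85) {
  at <- model$atoms
  res <- data.frame(donor_residue_id = integer(0),
                    acceptor_residue_id = integer(0), X = integer(0))
  c1s <- which(toupper(at$name) == "C1")
  for (ci in c1s) {
    p1 <- c(at$x[ci], at$y[ci], at$z[ci])
    ox <- atoms_within(at, p1, cutoff, element_prefix = "O")
    ox <- ox[at$residue_number[ox] != at$residue_number[ci]]
    for (oi in ox) {
      po <- c(at$x[oi], at$y[oi], at$z[oi])
      cc <- atoms_within(at, po, cutoff, element_prefix = "C")
      cc <- cc[at$residue_number[cc] != at$residue_number[ci] &
               toupper(at$name[cc]) %in% c("C3", "C4")]
      if (length(cc) == 0) next
      if (length(cc) > 1) {
        warning(sprintf(
          "find_glycosidic_linkages: ambiguous bridge at O serial %d; using nearest candidate",
          at$serial[oi]))
        dcc <- sqrt((at$x[cc] - po[1])^2 + (at$y[cc] - po[2])^2 +
                    (at$z[cc] - po[3])^2)
        cc <- cc[order(dcc)]
      }
      cc <- cc[1]
      res <- rbind(res, data.frame(
        donor_residue_id = at$residue_number[ci],
        acceptor_residue_id = at$residue_number[cc],
        X = as.integer(substr(toupper(at$name[cc]), 2, 2))))
    }
  }
  unique(res)
}

#' Per-residue ring pucker classification
#'
#' Extracts the six-membered ring (O5, C1..C5, honouring atom-name
#' synonyms) of every residue, computes Cremer-Pople parameters and the
#' nearest canonical pucker name. Residues without a complete ring are
#' skipped with a warning.
#'
#' @param model a [structure_model()].
#' @return data.frame with residue_id, residue_name, Q, theta, phi,
#'   pucker.
#' @export
classify_residue_puckers <- function(model) {
  at <- model$atoms
  out <- list()
  for (r in unique(at$residue_number)) {
    sub <- at[at$residue_number == r, , drop = FALSE]
    idx <- vapply(c("O5", "C1", "C2", "C3", "C4", "C5"),
                  function(a) resolve_ring_atom(sub$name, a), integer(1))
    if (anyNA(idx)) {
      warning(sprintf(
        "classify_residue_puckers: residue %s %d lacks a complete pyranose ring; skipped",
        sub$residue_name[1], r))
      next
    }
    cf <- ring_conformer(as.matrix(sub[idx, c("x", "y", "z")]),
                         source_tag = sprintf("residue %d", r))
    pp <- cremer_pople(cf)
    out[[length(out) + 1]] <- data.frame(
      residue_id = r, residue_name = sub$residue_name[1], Q = pp$Q,
      theta = pp$theta, phi = if (pp$phi_defined) pp$phi else NA_real_,
      pucker = pucker_name(pp))
  }
  if (length(out) == 0)
    return(data.frame(residue_id = integer(0), residue_name = character(0),
                      Q = numeric(0), theta = numeric(0), phi = numeric(0),
                      pucker = character(0)))
  do.call(rbind, out)
}
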