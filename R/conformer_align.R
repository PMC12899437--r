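#' Snapshot nearest to a torsion target
#'
#' Minimizer of the periodic Euclidean distance
#' sqrt(dphi^2 + dpsi^2) between each frame's (phi, psi) and the target;
#' ties go to the lowest frame id.
#'
#' @param series data.frame with columns `frame_id`, `phi`, `psi`.
#' @param target c(phi, psi) in degrees (or a list with `phi`, `psi`).
#' @return the selected `frame_id`, with the distance (degrees) as
#'   attribute `distance`.
#' @export
nearest_snapshot <- function(series, target) {
  if (is.list(target) && !is.null(target$phi)) target <- c(target$phi, target$psi)
  if (nrow(series) == 0) stop("nearest_snapshot: empty series")
  d <- sqrt(periodic_diff(series$phi, target[1])^2 +
            periodic_diff(series$psi, target[2])^2)
  ord <- order(d, series$frame_id)
  structure(series$frame_id[ord[1]], distance = d[ord[1]])
}

## fetch an n x 3 coordinate matrix for named atoms of one residue-or-model
atom_coords <- function(model, atom_names, residue = NULL) {
  at <- model$atoms
  if (!is.null(residue)) at <- at[at$residue_number == residue, , drop = FALSE]
  idx <- match(atom_names, at$name)
  if (anyNA(idx))
    stop("atoms not found: ", paste(atom_names[is.na(idx)], collapse = ", "))
  as.matrix(at[idx, c("x", "y", "z")])
}

#' Least-squares superposition on named atoms
#'
#' Kabsch algorithm: the proper rotation and translation minimizing the
#' RMSD of the named atom sets (same order in both structures). With
#' only a handful of atoms the problem can degenerate for near-collinear
#' sets; the singular-value spectrum of the covariance is checked and an
#' error raised when the rotation is not determined.
#'
#' @param mobile,reference structures (`structure_model` or plain n x 3
#'   coordinate matrices).
#' @param atom_names atoms to superpose; default the reducing-end
#'   anomeric set C1, O1, C2, O5 used for disaccharide comparisons.
#' @param residue_mobile,residue_reference optional residue numbers the
#'   atom names are looked up in.
#' @return object of class `alignment_result`: list with `rotation`
#'   (3 x 3, det +1), `translation`, `rmsd` (Angstrom), and
#'   `transform(x)`, a function applying the fit to an n x 3 matrix.
#' @export
superpose <- function(mobile, reference,
                      atom_names = c("C1", "O1", "C2", "O5"),
                      residue_mobile = NULL, residue_reference = NULL) {
  get_xyz <- function(s, res) {
    if (is.matrix(s)) s else atom_coords(s, atom_names, res)
  }
  X <- get_xyz(mobile, residue_mobile)      # mobile
  Y <- get_xyz(reference, residue_reference)
  if (nrow(X) != nrow(Y)) stop("superpose: atom count mismatch")
  if (nrow(X) < 3) stop("superpose: need at least 3 atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  if (sv$d[1] < 1e-12 || sv$d[2] / sv$d[1] < 1e-8)
    stop("superpose: near-collinear atom set, rotation degenerate")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)               # maps centered mobile onto reference
  Xfit <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xfit - Yc)^2)))
  translation <- as.numeric(cy - cx %*% t(R))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 transform = function(x) sweep(as.matrix(x) %*% t(R), 2,
                                               translation, `+`)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: rmsd %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to a whole structure model
#'
#' @param model a `structure_model`.
#' @param fit an [superpose()] result.
#' @return the model with transformed coordinates.
#' @export
apply_alignment <- function(model, fit) {
  xyz <- fit$transform(as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Divergence of a highlighted bond between two aligned structures
#'
#' After the structures have been superposed on their reducing-end
#' atoms, measures how the named bond (by default the non-reducing-end
#' C-O bond that would continue the glycan chain) differs: the angle
#' between the two bond unit vectors and the displacement of the
#' bond-origin atoms.
#'
#' @param a,b structures (`structure_model`), already superposed.
#' @param bond c(origin_atom, tip_atom) names, e.g. c("C4", "O4").
#' @param residue_a,residue_b optional residue numbers.
#' @return list with `angle` (degrees) and `origin_displacement`
#'   (Angstrom).
#' @export
bond_vector_divergence <- function(a, b, bond = c("C4", "O4"),
                                   residue_a = NULL, residue_b = NULL) {
  pa <- atom_coords(a, bond, residue_a)
  pb <- atom_coords(b, bond, residue_b)
  va <- pa[2, ] - pa[1, ]
  vb <- pb[2, ] - pb[1, ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-8 || nb < 1e-8)
    stop("bond_vector_divergence: zero-length bond")
  cosang <- sum(va * vb) / (na * nb)
  list(angle = rad2deg(acos(min(max(cosang, -1), 1))),
       origin_displacement = sqrt(sum((pa[1, ] - pb[1, ])^2)))
}
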