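## Internal-coordinate atom placement (natural extension reference frame):
## given positions A-B-C, place D bonded to C with bond length r, angle
## B-C-D = ang and torsion dihedral(A, B, C, D) = tor (degrees).
place_atom <- function(A, B, C, r, ang, tor) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("place_atom: collinear reference atoms")
  n <- n / nn
  m <- cross3(n, bc)
  a <- deg2rad(ang)
  t <- deg2rad(tor)
  C + r * (-cos(a) * bc + sin(a) * cos(t) * m + sin(a) * sin(t) * n)
}

## idealized bond lengths (Angstrom) and tetrahedral-ish angles for the
## geometric fixtures; these serve torsion/pucker logic, not energetics
BOND_CO <- 1.43
BOND_CC <- 1.52
BOND_CN <- 1.47
BOND_SO <- 1.60
ANG_TET <- 109.47

## substituent recipes per residue type: atom placed off chain A-B-C,
## in placement order (C6 must precede O6)
residue_recipe_full <- function(type) {
  two <- if (type == "IdoA")
    list(list(atom = "O2", chain = c("O5", "C1", "C2"), r = BOND_CO,
              tor = 120))
  else
    list(list(atom = "N2", chain = c("O5", "C1", "C2"), r = BOND_CN,
              tor = 120))
  c(two,
    list(list(atom = "O3", chain = c("C1", "C2", "C3"), r = BOND_CO,
              tor = -120),
         list(atom = "O4", chain = c("C2", "C3", "C4"), r = BOND_CO,
              tor = 120),
         list(atom = "C6", chain = c("C3", "C4", "C5"), r = BOND_CC,
              tor = -60),
         list(atom = "O6", chain = c("C4", "C5", "C6"), r = BOND_CO,
              tor = 180)))
}

## Build one residue's atoms. `pucker` is c(theta, phi, Q); `anchors`,
## when given, is list(C1 = xyz, O5 = xyz) fixing the placed ring.
build_residue_coords <- function(type, pucker, anchors = NULL,
                                 include_O1 = TRUE) {
  ring <- inverse_cremer_pople(pucker[3], pucker[1], pucker[2])
  co <- ring$coords
  rownames(co) <- ring$atom_labels
  if (!is.null(anchors)) {
    a <- co["C1", ]; b <- co["O5", ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    vtar <- anchors$O5 - anchors$C1
    v <- vtar / sqrt(sum(vtar^2))
    ## rotation taking u to v (Rodrigues); deterministic spin about v
    w <- cross3(u, v)
    s <- sqrt(sum(w^2)); cth <- sum(u * v)
    if (s < 1e-12) {
      R <- if (cth > 0) diag(3) else {
        ## opposite directions: rotate 180 about any perpendicular axis
        p <- if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
        p <- p / sqrt(sum(p^2))
        2 * outer(p, p) - diag(3)
      }
    } else {
      K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
      R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
    }
    co <- sweep(co, 2, a) %*% t(R)
    co <- sweep(co, 2, anchors$C1, `+`)
    rownames(co) <- ring$atom_labels
  }
  for (rec in residue_recipe_full(type)) {
    D <- place_atom(co[rec$chain[1], ], co[rec$chain[2], ],
                    co[rec$chain[3], ], rec$r, ANG_TET, rec$tor)
    co <- rbind(co, matrix(D, 1, 3, dimnames = list(rec$atom, NULL)))
  }
  if (include_O1) {
    D <- place_atom(co["C3", ], co["C2", ], co["C1", ], BOND_CO, ANG_TET, -60)
    co <- rbind(co, matrix(D, 1, 3, dimnames = list("O1", NULL)))
  }
  co
}

pucker_xyz <- function(pucker, Q = 0.57) {
  if (is.character(pucker)) pucker <- ido_pucker_states(pucker)
  if (inherits(pucker, "pucker_state")) {
    th <- if (is.na(pucker$theta0)) pucker$theta_ideal else pucker$theta0
    ph <- if (is.na(pucker$phi0)) {
      if (is.na(pucker$phi_ideal)) 0 else pucker$phi_ideal
    } else pucker$phi0
    c(th, ph, Q)
  } else as.numeric(pucker)
}

residue_display_name <- function(type, sulfated) {
  switch(type,
         IdoA = if ("O2" %in% sulfated) "IDS" else "IDU",
         GlcN = "SGN",
         GalNAc = if ("O4" %in% sulfated) "ASG" else "NGA")
}

## Chain builder. `residues` is a list of
##   list(type, pucker = c(theta, phi, Q), sulfate = c("O2", ...),
##        X = <attachment carbon on the PREVIOUS residue>, phi, psi)
## built from the reducing end (residue 1, which keeps its anomeric O1)
## towards the non-reducing end.
build_glycan_chain <- function(residues, chain = "A") {
  all_atoms <- list()
  prev <- NULL
  for (k in seq_along(residues)) {
    r <- residues[[k]]
    if (k == 1) {
      co <- build_residue_coords(r$type, r$pucker, include_O1 = TRUE)
    } else {
      ox_name <- paste0("O", r$X)
      cx_name <- paste0("C", r$X)
      cw_name <- paste0("C", r$X - 1)
      OX <- prev[ox_name, ]; CX <- prev[cx_name, ]; CW <- prev[cw_name, ]
      ring_side <- sqrt(sum((inverse_cremer_pople(r$pucker[3], r$pucker[1],
                                                  r$pucker[2])$coords[1, ] -
                             inverse_cremer_pople(r$pucker[3], r$pucker[1],
                                                  r$pucker[2])$coords[2, ])^2))
      C1p <- place_atom(CW, CX, OX, BOND_CO, 116, r$psi)
      O5p <- place_atom(CX, OX, C1p, ring_side, 113, r$phi)
      co <- build_residue_coords(r$type, r$pucker,
                                 anchors = list(C1 = C1p, O5 = O5p),
                                 include_O1 = FALSE)
    }
    for (s in r$sulfate) {
      parentC <- sub("O", "C", s)
      refC <- if (s == "O6") "C5" else
        paste0("C", as.integer(substr(s, 2, 2)) - 1)
      if (s == "O2") refC <- "C1"
      D <- place_atom(co[refC, ], co[parentC, ], co[s, ], BOND_SO, 115, 180)
      co <- rbind(co, matrix(D, 1, 3,
                             dimnames = list(sub("O", "S", s), NULL)))
    }
    all_atoms[[k]] <- data.frame(
      name = rownames(co), residue_name = residue_display_name(r$type,
                                                               r$sulfate),
      residue_number = k, x = co[, 1], y = co[, 2], z = co[, 3],
      stringsAsFactors = FALSE, row.names = NULL)
    prev <- co
  }
  at <- do.call(rbind, all_atoms)
  at$serial <- seq_len(nrow(at))
  at$chain <- chain
  structure_model(at[, c("serial", "name", "residue_name", "chain",
                         "residue_number", "x", "y", "z")])
}

## Table of template/sulfation-site definitions. `amino` marks the
## amino-sugar residue (GlcN or GalNAc), `ido` the iduronate; R1..R3 name
## the three variable hydroxyl positions.
DISACCHARIDE_TEMPLATES <- list(
  HS1 = list(donor = "IdoA", acceptor = "GlcN", X = 4,
             codes = list("1" = character(0), "2" = "R3",
                          "3" = c("R2", "R3"), "4" = c("R1", "R2", "R3")),
             sites = list(R1 = c("amino", "O3"), R2 = c("amino", "O6"),
                          R3 = c("ido", "O2"))),
  HS2 = list(donor = "GlcN", acceptor = "IdoA", X = 4,
             codes = list("1" = character(0), "2" = "R3",
                          "3" = c("R2", "R3"), "4" = c("R1", "R2", "R3")),
             sites = list(R1 = c("amino", "O3"), R2 = c("amino", "O6"),
                          R3 = c("ido", "O2"))),
  DS1 = list(donor = "IdoA", acceptor = "GalNAc", X = 3,
             codes = list(a = "R1", b = c("R1", "R3"), d = c("R2", "R3"),
                          e = c("R1", "R2")),
             sites = list(R1 = c("amino", "O4"), R2 = c("amino", "O6"),
                          R3 = c("ido", "O2"))),
  DS2 = list(donor = "GalNAc", acceptor = "IdoA", X = 4,
             codes = list(a = "R1", b = c("R1", "R3"), d = c("R2", "R3"),
                          e = c("R1", "R2")),
             sites = list(R1 = c("amino", "O4"), R2 = c("amino", "O6"),
                          R3 = c("ido", "O2"))))

#' Sulfation codes admitted by a disaccharide template
#'
#' @param template "HS1", "HS2", "DS1" or "DS2".
#' @return character vector of valid codes (n = 1-4 for heparin/HS,
#'   x = a/b/d/e for dermatan sulfate).
#' @export
sulfation_codes <- function(template) {
  tpl <- DISACCHARIDE_TEMPLATES[[template]]
  if (is.null(tpl)) stop("sulfation_codes: unknown template ", template)
  names(tpl$codes)
}

#' Idealized-geometry disaccharide fixture
#'
#' Builds a two-residue glycan with idealized internal coordinates: the
#' iduronate ring at the requested Cremer-Pople pucker (reference
#' near-ideal coordinates), the amino sugar at 4C1, the glycosidic
#' torsions set exactly to (phi, psi), and sulfate groups per the
#' template's sulfation code. Templates follow the four
#' GAG-disaccharide patterns: HS1 = IdoA-alpha-1,4-GlcNS, HS2 =
#' GlcNS-alpha-1,4-IdoA, DS1 = IdoA-alpha-1,3-GalNAc (X = 3), DS2 =
#' GalNAc-beta-1,4-IdoA. The fixture serves torsion/pucker logic
#' (geometry is idealized, not force-field accurate); residue 1 is the
#' reducing end.
#'
#' @param template one of "HS1", "HS2", "DS1", "DS2".
#' @param sulfation sulfation code: "1".."4" (HS) or "a"/"b"/"d"/"e"
#'   (DS).
#' @param pucker iduronate pucker: a [pucker_state()], a state name, or
#'   c(theta, phi, Q).
#' @param phi,psi glycosidic torsions, degrees.
#' @return a [structure_model()] with residues 1 (acceptor, reducing
#'   end) and 2 (donor).
#' @export
build_disaccharide_fixture <- function(template, sulfation = "1",
                                       pucker = "1C4",
                                       phi = -77.5, psi = 132.5) {
  tpl <- DISACCHARIDE_TEMPLATES[[template]]
  if (is.null(tpl))
    stop("build_disaccharide_fixture: unknown template ", template)
  sulfation <- as.character(sulfation)
  if (!sulfation %in% names(tpl$codes))
    stop(sprintf("build_disaccharide_fixture: unknown sulfation code '%s' for %s (valid: %s)",
                 sulfation, template,
                 paste(names(tpl$codes), collapse = ", ")))
  sulf_sites <- tpl$sites[tpl$codes[[sulfation]]]
  sulf_for <- function(role)
    vapply(sulf_sites[vapply(sulf_sites, `[`, "", 1) == role], `[`, "", 2)
  ido_pk <- pucker_xyz(pucker)
  c41 <- pucker_xyz("4C1")
  roles <- c(acceptor = tpl$acceptor, donor = tpl$donor)
  res_of_role <- function(role_type)
    if (role_type == "IdoA") "ido" else "amino"
  residues <- list(
    list(type = tpl$acceptor,
         pucker = if (tpl$acceptor == "IdoA") ido_pk else c41,
         sulfate = sulf_for(res_of_role(tpl$acceptor))),
    list(type = tpl$donor,
         pucker = if (tpl$donor == "IdoA") ido_pk else c41,
         sulfate = sulf_for(res_of_role(tpl$donor)),
         X = tpl$X, phi = phi, psi = psi))
  build_glycan_chain(residues)
}

#' Synthetic two-model heparin dodecasaccharide
#'
#' Geometric stand-in for the NMR-determined heparin dodecamer
#' [-4IdoA2S-alpha-1,4-GlcNS6S-alpha-1,4-]6: twelve alternating
#' IdoA2S/GlcNS6S residues built with idealized internal coordinates.
#' Model 1 places every IdoA2S ring in the 2SO skew-boat with
#' IdoA2S->GlcNS6S linkages at (phi, psi) = (-55, 135) and
#' GlcNS6S->IdoA2S linkages at (108, 83); model 2 uses the 1C4 chair
#' with (-77, 133) and (79, 88) -- the published per-model consensus
#' torsions of the two NMR structure models. This is a synthetic
#' construction for exercising the analysis pipeline, not experimental
#' coordinates.
#'
#' @param n_residues chain length (even, >= 2).
#' @return list of two [structure_model()] objects (model 1 = 2SO,
#'   model 2 = 1C4).
#' @export
build_heparin_dodecamer <- function(n_residues = 12) {
  stopifnot(n_residues >= 2, n_residues %% 2 == 0)
  one_model <- function(ido_state, hs1_tors, hs2_tors) {
    ido_pk <- pucker_xyz(ido_state)
    c41 <- pucker_xyz("4C1")
    residues <- vector("list", n_residues)
    for (k in seq_len(n_residues)) {
      is_glcn <- k %% 2 == 1   # reducing end (residue 1) is GlcNS6S
      if (is_glcn) {
        residues[[k]] <- list(type = "GlcN", pucker = c41, sulfate = "O6")
      } else {
        residues[[k]] <- list(type = "IdoA", pucker = ido_pk,
                              sulfate = "O2")
      }
      if (k > 1) {
        tors <- if (is_glcn) hs2_tors else hs1_tors
        residues[[k]]$X <- 4
        residues[[k]]$phi <- tors[1]
        residues[[k]]$psi <- tors[2]
      }
    }
    build_glycan_chain(residues)
  }
  m1 <- one_model("2SO", hs1_tors = c(-55, 135), hs2_tors = c(108, 83))
  m2 <- one_model("1C4", hs1_tors = c(-77, 133), hs2_tors = c(79, 88))
  m1$model_id <- 1L
  m2$model_id <- 2L
  list(m1, m2)
}
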