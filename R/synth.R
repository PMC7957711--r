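# Deterministic synthetic receptor-ligand complexes with ground truth.
#
# The generator builds ideal peptides from internal coordinates (helix
# phi=-57, psi=-47; extended phi=psi=180) with coarse single-rotamer side
# chains, then plants a complex: the ligand strand is placed at a fixed gap
# from the receptor helix and selected receptor side chains are rotated about
# their CB onto the sphere-sphere intersection that puts the interacting atom
# at an EXACT planted distance from its ligand partner. Every planted
# interaction therefore satisfies its detector threshold with a stated
# margin, and all other cross-chain residue pairs are verified to stay beyond
# 5.5 A, so the expected detector output is known by construction.

AA_CODE <- c(A = "ALA", G = "GLY", L = "LEU", V = "VAL", K = "LYS", R = "ARG",
             D = "ASP", E = "GLU", S = "SER", N = "ASN", Q = "GLN", F = "PHE",
             Y = "TYR", W = "TRP", H = "HIS")

# 2D regular-polygon ring template: first vertex at the origin, ring center
# on the +x axis; returns n x 2 matrix walking the ring.
ring_template_2d <- function(n, side) {
  r <- side / (2 * sin(pi / n))
  th <- pi - 2 * pi * (seq_len(n) - 1) / n
  cbind(r + r * cos(th), r * sin(th))
}

# Map 2D template points into 3D: origin + x*u + y*v
map_ring <- function(tmpl, origin, u, v) {
  t(apply(tmpl, 1, function(p) origin + p[1] * u + p[2] * v))
}

# local frame for ring construction at a gamma atom
ring_frame <- function(cb, cg, ca) {
  u <- cg - cb; u <- u / sqrt(sum(u^2))
  w <- cb - ca
  v <- w - sum(w * u) * u
  if (sqrt(sum(v^2)) < 1e-6) v <- c(u[2], -u[1], 0)
  v <- v / sqrt(sum(v^2))
  list(u = u, v = v)
}

# side-chain atom recipes; each entry: name, then (a, b, c) references among
# already-placed atoms, bond length, angle, dihedral
build_side_chain <- function(res3, pos) {
  N <- pos[["N"]]; CA <- pos[["CA"]]; C <- pos[["C"]]
  out <- list()
  if (res3 == "GLY") return(out)
  CB <- place_atom(N, C, CA, 1.53, 110.4, -122.5)
  out[["CB"]] <- CB
  g <- function(L, ang, chi = 180) place_atom(N, CA, CB, L, ang, chi)
  add_ring <- function(names6, tmpl, CG) {
    fr <- ring_frame(CB, CG, CA)
    xyz <- map_ring(tmpl, CG, fr$u, fr$v)
    for (k in seq_along(names6)) out[[names6[k]]] <<- xyz[k, ]
  }
  switch(res3,
    ALA = {},
    SER = { out[["OG"]] <- g(1.417, 110.8) },
    VAL = { out[["CG1"]] <- g(1.52, 110.5, 180); out[["CG2"]] <- g(1.52, 110.5, -60) },
    LEU = {
      CG <- g(1.53, 116.3); out[["CG"]] <- CG
      out[["CD1"]] <- place_atom(CA, CB, CG, 1.52, 110.7, 180)
      out[["CD2"]] <- place_atom(CA, CB, CG, 1.52, 110.7, 60)
    },
    LYS = {
      CG <- g(1.52, 114); out[["CG"]] <- CG
      CD <- place_atom(CA, CB, CG, 1.52, 111, 180); out[["CD"]] <- CD
      CE <- place_atom(CB, CG, CD, 1.52, 111, 180); out[["CE"]] <- CE
      out[["NZ"]] <- place_atom(CG, CD, CE, 1.47, 112, 180)
    },
    ARG = {
      CG <- g(1.52, 114); out[["CG"]] <- CG
      CD <- place_atom(CA, CB, CG, 1.52, 111, 180); out[["CD"]] <- CD
      NE <- place_atom(CB, CG, CD, 1.46, 112, 180); out[["NE"]] <- NE
      CZ <- place_atom(CG, CD, NE, 1.33, 124, 180); out[["CZ"]] <- CZ
      out[["NH1"]] <- place_atom(CD, NE, CZ, 1.33, 120, 0)
      out[["NH2"]] <- place_atom(CD, NE, CZ, 1.33, 120, 180)
    },
    ASP = {
      CG <- g(1.52, 112.6); out[["CG"]] <- CG
      out[["OD1"]] <- place_atom(CA, CB, CG, 1.25, 118.5, 180)
      out[["OD2"]] <- place_atom(CA, CB, CG, 1.25, 118.5, 0)
    },
    GLU = {
      CG <- g(1.52, 114); out[["CG"]] <- CG
      CD <- place_atom(CA, CB, CG, 1.52, 112.6, 180); out[["CD"]] <- CD
      out[["OE1"]] <- place_atom(CB, CG, CD, 1.25, 118.5, 180)
      out[["OE2"]] <- place_atom(CB, CG, CD, 1.25, 118.5, 0)
    },
    ASN = {
      CG <- g(1.52, 112.6); out[["CG"]] <- CG
      out[["OD1"]] <- place_atom(CA, CB, CG, 1.23, 120.8, 0)
      out[["ND2"]] <- place_atom(CA, CB, CG, 1.33, 116.4, 180)
    },
    GLN = {
      CG <- g(1.52, 114); out[["CG"]] <- CG
      CD <- place_atom(CA, CB, CG, 1.52, 112.6, 180); out[["CD"]] <- CD
      out[["OE1"]] <- place_atom(CB, CG, CD, 1.23, 120.8, 0)
      out[["NE2"]] <- place_atom(CB, CG, CD, 1.33, 116.4, 180)
    },
    PHE = , TYR = {
      CG <- g(1.50, 113.8); out[["CG"]] <- CG
      add_ring(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               ring_template_2d(6, 1.39), CG)
      if (res3 == "TYR") {
        fr <- ring_frame(CB, CG, CA)
        r6 <- 1.39 / (2 * sin(pi / 6))
        out[["OH"]] <- CG + (2 * r6 + 1.38) * fr$u
      }
    },
    HIS = {
      CG <- g(1.50, 113.8); out[["CG"]] <- CG
      add_ring(c("CG", "ND1", "CE1", "NE2", "CD2"),
               ring_template_2d(5, 1.37), CG)
    },
    TRP = {
      CG <- g(1.50, 113.8); out[["CG"]] <- CG
      pent <- ring_template_2d(5, 1.40) # CG CD1 NE1 CE2 CD2
      fr <- ring_frame(CB, CG, CA)
      xyz5 <- map_ring(pent, CG, fr$u, fr$v)
      nm5 <- c("CG", "CD1", "NE1", "CE2", "CD2")
      for (k in 1:5) out[[nm5[k]]] <- xyz5[k, ]
      # fused hexagon on the CE2-CD2 edge, pointing away from the pentagon
      ce2 <- xyz5[4, ]; cd2 <- xyz5[5, ]
      mid <- (ce2 + cd2) / 2
      cen5 <- colMeans(xyz5)
      away <- mid - cen5; away <- away / sqrt(sum(away^2))
      cen6 <- mid + 1.40 * sqrt(3) / 2 * away
      edge <- ce2 - cd2; edge <- edge / sqrt(sum(edge^2))
      # hexagon vertices by rotating (CE2 - center) in the ring plane; the
      # rotation sign must walk away from CD2, not onto it
      nrm <- vector_cross(edge, away)
      start <- ce2 - cen6
      sgn <- 1
      if (sqrt(sum((cen6 + rotate_about_axis(start, nrm, pi / 3) - cd2)^2)) < 0.5) {
        sgn <- -1
      }
      for (k in 1:4) {
        v <- rotate_about_axis(start, nrm, sgn * pi / 3 * k)
        out[[c("CZ2", "CH2", "CZ3", "CE3")[k]]] <- cen6 + v
      }
    },
    stop("unsupported residue: ", res3)
  )
  out
}

vector_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

rotate_about_axis <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + vector_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Build an ideal peptide Structure
#'
#' Constructs an all-heavy-atom peptide from internal coordinates with an
#' ideal backbone (helix: phi = -57, psi = -47; extended: phi = psi = 180)
#' and coarse single-rotamer side chains that place the functionally relevant
#' terminal atoms (Lys NZ, carboxylate oxygens, aromatic rings, ...) at
#' canonical geometry.
#'
#' @param sequence 1-letter string over A G L V K R D E S N Q F Y W H
#' @param conformation "helix" or "extended"
#' @param chain chain id
#' @param start_resno first residue number
#' @return Structure (untyped)
#' @export
make_peptide <- function(sequence, conformation = c("helix", "extended"),
                         chain = "A", start_resno = 1L) {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(sequence, "")[[1]]
  if (!length(letters1)) stop("make_peptide: empty sequence")
  bad <- setdiff(letters1, names(AA_CODE))
  if (length(bad)) {
    stop("make_peptide: unsupported residue letter(s): ",
         paste(unique(bad), collapse = ", "))
  }
  phi <- if (conformation == "helix") -57 else 180
  psi <- if (conformation == "helix") -47 else 180

  n_res <- length(letters1)
  res_atoms <- vector("list", n_res)
  # residue 1 backbone in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  C <- CA + 1.525 * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    pos <- list(N = N, CA = CA, C = C)
    if (i < n_res) {
      N_next <- place_atom(pos$N, pos$CA, pos$C, 1.329, 116.2, psi)
      CA_next <- place_atom(pos$CA, pos$C, N_next, 1.458, 121.7, 180)
      C_next <- place_atom(pos$C, N_next, CA_next, 1.525, 111.2, phi)
    }
    pos[["O"]] <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.8, psi + 180)
    sc <- build_side_chain(AA_CODE[[letters1[i]]], pos)
    res_atoms[[i]] <- c(pos[c("N", "CA", "C", "O")], sc)
    if (i < n_res) { N <- N_next; CA <- CA_next; C <- C_next }
  }

  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    for (nm in names(res_atoms[[i]])) {
      serial <- serial + 1L
      p <- res_atoms[[i]][[nm]]
      rows[[serial]] <- data.frame(
        record = "ATOM", serial = serial, name = nm, altloc = " ",
        resname = AA_CODE[[letters1[i]]], chain = chain,
        resno = start_resno + i - 1L, ins = "",
        x = p[1], y = p[2], z = p[3], occ = 1, bfac = 0,
        element = substr(nm, 1, 1), stringsAsFactors = FALSE
      )
    }
  }
  a <- do.call(rbind, rows)
  a$is_hydrogen <- FALSE
  a$is_het <- FALSE
  a$is_glycan <- FALSE
  new_structure(a, model_id = 1L,
                provenance = list(path = "synthetic", model_index = 1L))
}

# Attach a pyranose-like glycan ring (C1 C2 C3 C4 C5 O5 + hydroxyl O3 O4) to
# an Asn ND2, pointing along `direction`; returns the Structure with the NAG
# residue appended as HETATM.
attach_glycan <- function(s, asn_resno, resno = 1601L, direction = NULL) {
  a <- s$atoms
  sel <- a$resno == asn_resno & a$resname == "ASN"
  if (!any(sel)) stop("attach_glycan: no ASN at residue ", asn_resno)
  nd2 <- unlist(a[sel & a$name == "ND2", c("x", "y", "z")])
  cg <- unlist(a[sel & a$name == "CG", c("x", "y", "z")])
  if (is.null(direction)) direction <- nd2 - cg
  u <- direction / sqrt(sum(direction^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  c1 <- nd2 + 1.45 * u
  ring <- map_ring(ring_template_2d(6, 1.45), c1, u, v)
  nm <- c("C1", "C2", "C3", "C4", "C5", "O5")
  cen <- colMeans(ring)
  pts <- list()
  for (k in seq_along(nm)) pts[[nm[k]]] <- ring[k, ]
  for (k in c(3, 4)) { # hydroxyls on C3, C4, radially outward in-plane
    out_dir <- ring[k, ] - cen
    out_dir <- out_dir / sqrt(sum(out_dir^2))
    pts[[paste0("O", k)]] <- ring[k, ] + 1.43 * out_dir
  }
  serial0 <- max(a$serial)
  rows <- do.call(rbind, lapply(seq_along(pts), function(k) {
    p <- pts[[k]]
    data.frame(record = "HETATM", serial = serial0 + k, name = names(pts)[k],
               altloc = " ", resname = "NAG", chain = a$chain[1],
               resno = as.integer(resno), ins = "",
               x = p[1], y = p[2], z = p[3], occ = 1, bfac = 0,
               element = substr(names(pts)[k], 1, 1),
               is_hydrogen = FALSE, is_het = TRUE, is_glycan = TRUE,
               stringsAsFactors = FALSE)
  }))
  s$atoms <- rbind(a, rows)
  rownames(s$atoms) <- NULL
  s
}

# --- rigid alignment helpers -----------------------------------------------

# Align a peptide so its CA principal axis is +z (increasing resno) and the
# axis passes through the xy origin; CA of residue 1 at z = 0.
align_axis_z <- function(s) {
  a <- s$atoms
  ca <- as.matrix(a[a$name == "CA", c("x", "y", "z")])
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  axis <- sv$v[, 1]
  if (sum(axis * (ca[nrow(ca), ] - ca[1, ])) < 0) axis <- -axis
  R <- rotation_between(axis, c(0, 0, 1))
  xyz <- tcrossprod(sweep(as.matrix(a[, c("x", "y", "z")]), 2, cen), R)
  ca2 <- tcrossprod(sweep(ca, 2, cen), R)
  xyz <- sweep(xyz, 2, c(ca2[1, 1], ca2[1, 2], ca2[1, 3]))
  set_coords(s, xyz)
}

# Rotate a z-aligned structure about z so the mean xy-direction of the given
# residues' CB atoms points along `target_xy`.
orient_face <- function(s, resnos, target_xy = c(-1, 0)) {
  a <- s$atoms
  cb <- a[a$name == "CB" & a$resno %in% resnos, c("x", "y"), drop = FALSE]
  m <- colMeans(as.matrix(cb))
  th_cur <- atan2(m[2], m[1])
  th_tgt <- atan2(target_xy[2], target_xy[1])
  th <- th_tgt - th_cur
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  set_coords(s, tcrossprod(coords(s), R))
}

side_chain_rows <- function(a, resno) {
  which(a$resno == resno & !a$is_het &
          !(a$name %in% c("N", "CA", "C", "O", "CB")))
}

atom_xyz <- function(a, resno, name) {
  r <- which(a$resno == resno & a$name == name)[1]
  if (is.na(r)) stop("atom not found: ", name, " in residue ", resno)
  c(a$x[r], a$y[r], a$z[r])
}

# Rotate the side chain of `resno` (atoms beyond CB) about CB so the terminal
# atom's direction from CB becomes `dir`.
aim_side_chain_direction <- function(s, resno, terminal, dir) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  t0 <- atom_xyz(a, resno, terminal)
  u0 <- t0 - cb; u0 <- u0 / sqrt(sum(u0^2))
  u1 <- dir / sqrt(sum(dir^2))
  R <- rotation_between(u0, u1)
  rows <- side_chain_rows(a, resno)
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  xyz <- sweep(tcrossprod(sweep(xyz, 2, cb), R), 2, cb, "+")
  a$x[rows] <- xyz[, 1]; a$y[rows] <- xyz[, 2]; a$z[rows] <- xyz[, 3]
  s$atoms <- a
  s
}

# Rotate the side chain of `resno` about its CB so that the terminal atom
# lands exactly `dist` from `target` (sphere-sphere intersection; the
# in-plane solution closest to the direct CB->target direction, tilted
# towards `ref_dir` for determinism). When `avoid_xyz` is given, the side
# chain is afterwards rolled about the CB->terminal axis (terminal fixed, so
# the planted distance stays exact) to the orientation maximising the
# minimal clearance of its remaining atoms from those points.
# Errors when unsatisfiable.
aim_side_chain_at <- function(s, resno, terminal, target, dist,
                              ref_dir = c(0, 1, 0), avoid_xyz = NULL) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  t0 <- atom_xyz(a, resno, terminal)
  ell <- sqrt(sum((t0 - cb)^2))
  L <- sqrt(sum((target - cb)^2))
  if (L > dist + ell - 1e-9 || L < abs(dist - ell) + 1e-9) {
    stop(sprintf(
      "aim_side_chain_at: unsatisfiable geometry for residue %d (reach %.2f, need |CB-target| in [%.2f, %.2f], have %.2f)",
      resno, ell, abs(dist - ell), dist + ell, L))
  }
  e <- (target - cb) / L
  cos_alpha <- (L^2 + ell^2 - dist^2) / (2 * L * ell)
  cos_alpha <- pmin(1, pmax(-1, cos_alpha))
  sin_alpha <- sqrt(1 - cos_alpha^2)
  f1 <- ref_dir - sum(ref_dir * e) * e
  if (sqrt(sum(f1^2)) < 1e-6) f1 <- c(e[2], -e[1], 0)
  f1 <- f1 / sqrt(sum(f1^2))
  f2 <- vector_cross(e, f1)
  # the admissible terminal positions form a circle; pick the point farthest
  # from the avoid set (falling back to the ref_dir side when unconstrained)
  t_new <- NULL
  if (!is.null(avoid_xyz)) {
    best <- -Inf
    for (k in 0:71) {
      th <- 2 * pi * k / 72
      cand <- cb + ell * (cos_alpha * e +
                            sin_alpha * (cos(th) * f1 + sin(th) * f2))
      sc <- min(cross_dist2(matrix(cand, 1), avoid_xyz))
      if (sc > best + 1e-12) { best <- sc; t_new <- cand }
    }
  } else {
    t_new <- cb + ell * (cos_alpha * e + sin_alpha * f1)
  }
  s <- aim_side_chain_direction(s, resno, terminal, t_new - cb)
  if (!is.null(avoid_xyz)) s <- roll_for_clearance(s, resno, terminal, avoid_xyz)
  s
}

# Discrete roll search about the CB->terminal axis: pick the roll (of 48)
# whose non-terminal side-chain atoms have the largest minimal distance to
# `avoid_xyz`. Deterministic; ties resolved by the first best angle.
roll_for_clearance <- function(s, resno, terminal, avoid_xyz, n_angles = 48) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  tt <- atom_xyz(a, resno, terminal)
  axis <- tt - cb
  if (sqrt(sum(axis^2)) < 1e-9) return(s)
  rows <- side_chain_rows(a, resno)
  rows <- rows[a$name[rows] != terminal]
  if (!length(rows)) return(s)
  xyz <- as.matrix(a[rows, c("x", "y", "z"), drop = FALSE])
  best <- NULL
  for (k in seq_len(n_angles) - 1L) {
    ang <- 2 * pi * k / n_angles
    cand <- t(apply(xyz, 1, function(p) cb + rotate_about_axis(p - cb, axis, ang)))
    score <- min(cross_dist2(cand, avoid_xyz))
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(score = score, cand = cand)
    }
  }
  a$x[rows] <- best$cand[, 1]; a$y[rows] <- best$cand[, 2]
  a$z[rows] <- best$cand[, 3]
  s$atoms <- a
  s
}

# Rotate a ring-bearing side chain about CB so the ring centroid direction
# from CB becomes `dir`.
aim_ring_direction <- function(s, resno, dir) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  rg <- ring_centroid_normal(a, resno)
  R <- rotation_between(rg$centroid - cb, dir)
  rows <- side_chain_rows(a, resno)
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  xyz <- sweep(tcrossprod(sweep(xyz, 2, cb), R), 2, cb, "+")
  a$x[rows] <- xyz[, 1]; a$y[rows] <- xyz[, 2]; a$z[rows] <- xyz[, 3]
  s$atoms <- a
  s
}

# Roll a ring about its CB->centroid axis so the ring normal points as
# closely as possible at `point` (exact when the point is perpendicular to
# the axis; the residual angle is checked by the construction verifier).
roll_ring_towards <- function(s, resno, point) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  rg <- ring_centroid_normal(a, resno)
  axis <- rg$centroid - cb; axis <- axis / sqrt(sum(axis^2))
  w <- point - rg$centroid
  n_opt <- w - sum(w * axis) * axis
  if (sqrt(sum(n_opt^2)) < 1e-6) return(s)
  n_opt <- n_opt / sqrt(sum(n_opt^2))
  n0 <- rg$normal - sum(rg$normal * axis) * axis
  n0 <- n0 / sqrt(sum(n0^2))
  cosr <- pmin(1, pmax(-1, sum(n0 * n_opt)))
  sinr <- sum(vector_cross(n0, n_opt) * axis)
  roll <- atan2(sinr, cosr)
  rows <- side_chain_rows(a, resno)
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  xyz <- t(apply(xyz, 1, function(p) cb + rotate_about_axis(p - cb, axis, roll)))
  a$x[rows] <- xyz[, 1]; a$y[rows] <- xyz[, 2]; a$z[rows] <- xyz[, 3]
  s$atoms <- a
  s
}

ring_atoms_of <- function(a, resno) {
  rn <- a$resname[a$resno == resno & !a$is_het][1]
  rings <- AROMATIC_RINGS[[rn]]
  rings[[length(rings)]] # for Trp: the benzene ring (longer reach from CB)
}

ring_centroid_normal <- function(a, resno) {
  nms <- ring_atoms_of(a, resno)
  xyz <- t(vapply(nms, function(nm) atom_xyz(a, resno, nm), numeric(3)))
  cen <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, cen))
  list(centroid = cen, normal = sv$v[, 3])
}

# Aim an aromatic side chain: ring centroid at exactly `dist` from `target`,
# then roll about the CB-centroid axis so the ring normal points as closely
# as possible at the target (exactly, when |CB-target| permits).
aim_ring_at <- function(s, resno, target, dist, ref_dir = c(0, 1, 0),
                        avoid_xyz = NULL) {
  a <- s$atoms
  cb <- atom_xyz(a, resno, "CB")
  rg <- ring_centroid_normal(a, resno)
  ell <- sqrt(sum((rg$centroid - cb)^2))
  L <- sqrt(sum((target - cb)^2))
  if (L > dist + ell - 1e-9 || L < abs(dist - ell) + 1e-9) {
    stop(sprintf("aim_ring_at: unsatisfiable for residue %d (L %.2f)", resno, L))
  }
  e <- (target - cb) / L
  cos_alpha <- pmin(1, pmax(-1, (L^2 + ell^2 - dist^2) / (2 * L * ell)))
  sin_alpha <- sqrt(1 - cos_alpha^2)
  f1 <- ref_dir - sum(ref_dir * e) * e
  if (sqrt(sum(f1^2)) < 1e-6) f1 <- c(e[2], -e[1], 0)
  f1 <- f1 / sqrt(sum(f1^2))
  f2 <- vector_cross(e, f1)
  cen_new <- cb + ell * (cos_alpha * e + sin_alpha * f1)
  if (!is.null(avoid_xyz)) {
    best <- -Inf
    for (k in 0:23) {
      th <- 2 * pi * k / 24
      cand <- cb + ell * (cos_alpha * e +
                            sin_alpha * (cos(th) * f1 + sin(th) * f2))
      sc <- min(cross_dist2(matrix(cand, 1), avoid_xyz))
      if (sc > best + 1e-12) { best <- sc; cen_new <- cand }
    }
  }
  # rotate the whole side chain about CB so the centroid lands on cen_new
  a <- s$atoms
  R <- rotation_between(rg$centroid - cb, cen_new - cb)
  rows <- side_chain_rows(a, resno)
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  xyz <- sweep(tcrossprod(sweep(xyz, 2, cb), R), 2, cb, "+")
  a$x[rows] <- xyz[, 1]; a$y[rows] <- xyz[, 2]; a$z[rows] <- xyz[, 3]
  s$atoms <- a
  # roll: align normal with the projection of (target - centroid) onto the
  # plane perpendicular to the CB->centroid axis
  rg <- ring_centroid_normal(s$atoms, resno)
  axis <- (rg$centroid - cb); axis <- axis / sqrt(sum(axis^2))
  w <- target - rg$centroid; w <- w / sqrt(sum(w^2))
  n_opt <- w - sum(w * axis) * axis
  if (sqrt(sum(n_opt^2)) < 1e-6) {
    return(s) # target along the axis: any roll is equivalent
  }
  n_opt <- n_opt / sqrt(sum(n_opt^2))
  n0 <- rg$normal - sum(rg$normal * axis) * axis
  n0 <- n0 / sqrt(sum(n0^2))
  cosr <- pmin(1, pmax(-1, sum(n0 * n_opt)))
  sinr <- sum(vector_cross(n0, n_opt) * axis)
  roll <- atan2(sinr, cosr)
  rows <- side_chain_rows(s$atoms, resno)
  a <- s$atoms
  xyz <- as.matrix(a[rows, c("x", "y", "z")])
  xyz <- t(apply(xyz, 1, function(p) cb + rotate_about_axis(p - cb, axis, roll)))
  a$x[rows] <- xyz[, 1]; a$y[rows] <- xyz[, 2]; a$z[rows] <- xyz[, 3]
  s$atoms <- a
  s
}

#' Specification of the standard synthetic complex
#'
#' The default spec plants one interaction of each kind between a 26-residue
#' receptor helix (chain A, with an N-linked glycan stand-in on Asn 7) and a
#' 10-residue extended ligand peptide (chain B): a salt bridge Glu 2 - Lys 1
#' at 3.5 A, a hydrogen bond Gln 9 (NE2) - Ser 4 (OG) at 2.9 A, a hydrophobic
#' contact Leu 16 (CD1) - Val 7 (CG1) at 4.0 A, and a pi-cation pair
#' Phe 23 (ring) - Lys 10 (NZ) at 4.0 A. The seed jitters the rigid ligand
#' placement (gap and axial offset) only; planted distances are exact by
#' construction.
#'
#' @param seed integer; deterministically perturbs the ligand placement
#' @param gap nominal receptor-axis to ligand-axis distance, Angstrom
#' @param glycan include the NAG stand-in on Asn 7
#' @return SyntheticComplexSpec object
#' @export
synthetic_complex_spec <- function(seed = 1L, gap = 14.0, glycan = TRUE) {
  structure(list(
    receptor_seq = "ARAAGQNAFGAGRA",
    ligand_seq = "AEGAGSAALGAGAW",
    lig_conformation = "helix",
    gap = gap, seed = as.integer(seed), glycan = glycan,
    lig_z_offset = 0.0,
    planted = list(
      list(kind = "salt_bridge", rec_resno = 2L, rec_atom = "NH1",
           lig_resno = 2L, lig_atom = "OE1", distance = 3.5),
      list(kind = "hbond", rec_resno = 6L, rec_atom = "NE2",
           lig_resno = 6L, lig_atom = "OG", distance = 2.9),
      list(kind = "hydrophobic", rec_resno = 9L, rec_atom = "CZ",
           lig_resno = 9L, lig_atom = "CD1", distance = 4.2),
      list(kind = "pi_cation", rec_resno = 13L, rec_atom = "NH1",
           lig_resno = 14L, lig_atom = "ring", distance = 4.2)
    )
  ), class = "SyntheticComplexSpec")
}

#' Build a planted receptor-ligand complex with ground truth
#'
#' Constructs the receptor helix and ligand strand of the spec, places the
#' ligand rigidly, rotates the planted receptor side chains about their CB so
#' every planted interaction sits at its exact distance (rings additionally
#' rolled so the normal points at the cation), and verifies the construction
#' invariants: planted distances to 1e-6 A, detector thresholds met with
#' >= 0.3 A margin, and all non-planted cross-chain residue pairs beyond
#' 5.5 A. Deterministic for a fixed seed.
#'
#' @param spec SyntheticComplexSpec
#' @return list(receptor, ligand, truth); both structures typed. The ligand
#'   as emitted IS the planted optimal pose. \code{truth} holds
#'   \code{contacts} (data.frame kind/rec_resno/lig_resno/distance, including
#'   hydrogen bonds implied by planted salt bridges), \code{rrcs_pairs},
#'   \code{interface_rec}/\code{interface_lig} residue numbers and the
#'   planted \code{pose} (identity).
#' @export
plant_complex <- function(spec = synthetic_complex_spec()) {
  stopifnot(inherits(spec, "SyntheticComplexSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  gap <- spec$gap + stats::runif(1, -0.2, 0.2)
  z_off <- spec$lig_z_offset + stats::runif(1, -0.4, 0.4)

  rec <- make_peptide(spec$receptor_seq, "helix", chain = "A")
  rec <- align_axis_z(rec)
  rec_planted <- vapply(spec$planted, function(p) p$rec_resno, integer(1))
  rec <- orient_face(rec, rec_planted, target_xy = c(-1, 0))
  if (spec$glycan) {
    nd2 <- atom_xyz(rec$atoms, 7L, "ND2")
    away <- c(nd2[1], nd2[2], 0)
    away <- away / sqrt(sum(away^2))
    rec <- attach_glycan(rec, 7L, resno = 1601L, direction = away)
  }

  lig_planted <- vapply(spec$planted, function(p) p$lig_resno, integer(1))
  lig <- make_peptide(spec$ligand_seq, spec$lig_conformation, chain = "B")
  lig <- align_axis_z(lig)
  lig <- orient_face(lig, lig_planted, target_xy = c(1, 0))
  xyz <- coords(lig)
  xyz[, 1] <- xyz[, 1] - gap
  xyz[, 3] <- xyz[, 3] + z_off
  lig <- set_coords(lig, xyz)

  # pose planted ligand side chains: the lysine rises out of the slot (+z),
  # serine and leucine point at wall 2 (+x)
  lig_dirs <- list(
    salt_bridge = c(0.5, 1, -0.5), hbond = c(1, 0, 0),
    hydrophobic = c(1, 0.4, 0), pi_cation = c(0.8, 0.6, 0.6)
  )
  terminal_of <- function(s, resno) {
    rn <- s$atoms$resname[s$atoms$resno == resno & !s$atoms$is_het][1]
    switch(rn, LYS = "NZ", SER = "OG", VAL = "CG1", LEU = "CD1",
           GLU = "OE1", ASP = "OD1", TRP = "ring",
           stop("no terminal rule for ", rn))
  }
  for (p in spec$planted) {
    if (p$lig_atom == "ring") {
      lig <- aim_ring_direction(lig, p$lig_resno, lig_dirs[[p$kind]])
    } else {
      lig <- aim_side_chain_direction(lig, p$lig_resno,
                                      terminal_of(lig, p$lig_resno),
                                      lig_dirs[[p$kind]])
    }
  }

  # aim receptor side chains at their exact planted distances (rings first,
  # since a ligand-ring roll moves ligand atoms other arms may target)
  ord <- order(vapply(spec$planted, function(p) p$kind != "pi_cation",
                      logical(1)))
  for (p in spec$planted[ord]) {
    avoid <- lig$atoms[lig$atoms$resno != p$lig_resno, c("x", "y", "z")]
    if (p$kind == "pi_cation" && p$lig_atom == "ring") {
      rg <- ring_centroid_normal(lig$atoms, p$lig_resno)
      ring_xyz <- t(vapply(ring_atoms_of(lig$atoms, p$lig_resno),
                           function(nm) atom_xyz(lig$atoms, p$lig_resno, nm),
                           numeric(3)))
      rec <- aim_side_chain_at(rec, p$rec_resno, p$rec_atom, rg$centroid,
                               p$distance,
                               avoid_xyz = rbind(as.matrix(avoid), ring_xyz))
      cation <- atom_xyz(rec$atoms, p$rec_resno, p$rec_atom)
      lig <- roll_ring_towards(lig, p$lig_resno, cation)
    } else if (p$kind == "pi_cation") {
      # receptor-side ring aimed at a ligand cation; the cation residue's
      # aliphatic tail joins the clearance set
      target <- atom_xyz(lig$atoms, p$lig_resno, p$lig_atom)
      tail <- lig$atoms[lig$atoms$resno == p$lig_resno &
                          !(lig$atoms$name %in% c(p$lig_atom, "CE")),
                        c("x", "y", "z")]
      rec <- aim_ring_at(rec, p$rec_resno, target, p$distance,
                         avoid_xyz = as.matrix(rbind(avoid, tail)))
    } else {
      target <- atom_xyz(lig$atoms, p$lig_resno, p$lig_atom)
      partner <- lig$atoms[lig$atoms$resno == p$lig_resno &
                             lig$atoms$name != p$lig_atom, c("x", "y", "z")]
      rec <- aim_side_chain_at(rec, p$rec_resno, p$rec_atom, target,
                               p$distance,
                               avoid_xyz = as.matrix(rbind(avoid, partner)))
    }
  }

  rec <- assign_atom_types(rec)
  lig <- assign_atom_types(lig)

  # ---- construction verification ----
  tol <- 1e-6
  margins <- c(salt_bridge = 4.0, hbond = 3.5, hydrophobic = 4.5,
               pi_cation = 6.0)
  planted_pairs <- character(0)
  for (p in spec$planted) {
    d <- if (p$kind == "pi_cation") {
      if (p$lig_atom == "ring") {
        rg <- ring_centroid_normal(lig$atoms, p$lig_resno)
        sqrt(sum((rg$centroid -
                    atom_xyz(rec$atoms, p$rec_resno, p$rec_atom))^2))
      } else {
        rg <- ring_centroid_normal(rec$atoms, p$rec_resno)
        sqrt(sum((rg$centroid -
                    atom_xyz(lig$atoms, p$lig_resno, p$lig_atom))^2))
      }
    } else {
      sqrt(sum((atom_xyz(rec$atoms, p$rec_resno, p$rec_atom) -
                  atom_xyz(lig$atoms, p$lig_resno, p$lig_atom))^2))
    }
    if (abs(d - p$distance) > tol) {
      stop(sprintf("plant_complex: %s planted at %.6f, wanted %.6f", p$kind, d,
                   p$distance))
    }
    if (d > margins[[p$kind]] - 0.3 + 1e-6) {
      stop(sprintf("plant_complex: %s margin violated (%.2f vs %.2f)", p$kind,
                   d, margins[[p$kind]]))
    }
    planted_pairs <- c(planted_pairs, paste(p$rec_resno, p$lig_resno))
  }
  # non-planted cross-chain residue pairs must stay beyond 5.5 A
  ra <- rec$atoms[!rec$atoms$is_hydrogen, ]
  la <- lig$atoms[!lig$atoms$is_hydrogen, ]
  d <- sqrt(cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                        as.matrix(la[, c("x", "y", "z")])))
  pair_id <- outer(ra$resno, la$resno, paste)
  off <- !(pair_id %in% planted_pairs)
  min_off <- min(d[off])
  if (min_off <= 5.5) {
    hit <- which(d == min_off & off, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "plant_complex: non-planted pair %s%d/%s - %s%d/%s at %.2f A (<= 5.5)",
      ra$resname[hit[1]], ra$resno[hit[1]], ra$name[hit[1]],
      la$resname[hit[2]], la$resno[hit[2]], la$name[hit[2]], min_off))
  }

  # cross-kind ambiguity checks: no residue pair may satisfy a detector it
  # was not planted for (pairs are allowed extra atom pairs of their own kind)
  planted_kind <- stats::setNames(
    vapply(spec$planted, `[[`, character(1), "kind"),
    vapply(spec$planted, function(p) paste(p$rec_resno, p$lig_resno),
           character(1)))
  check_clear <- function(mask_r, mask_l, lim, kinds_ok, label) {
    if (!any(mask_r) || !any(mask_l)) return(invisible())
    dd <- d[mask_r, mask_l, drop = FALSE]
    pp <- pair_id[mask_r, mask_l, drop = FALSE]
    bad <- dd <= lim & !(pp %in% names(planted_kind)[planted_kind %in% kinds_ok])
    if (any(bad)) {
      stop(sprintf("plant_complex: ambiguous %s geometry at %.2f A (pair %s)",
                   label, min(dd[bad]), pp[bad][which.min(dd[bad])]))
    }
  }
  check_clear(ra$is_hydrophobic, la$is_hydrophobic, 4.8,
              c("hydrophobic"), "hydrophobic")
  check_clear(ra$is_donor, la$is_acceptor, 3.8, c("hbond", "salt_bridge"),
              "donor-acceptor")
  check_clear(ra$is_acceptor, la$is_donor, 3.8, c("hbond", "salt_bridge"),
              "acceptor-donor")
  check_clear(ra$formal_charge_class == "cationic",
              la$formal_charge_class == "anionic", 4.3,
              c("salt_bridge"), "cation-anion")
  check_clear(ra$formal_charge_class == "anionic",
              la$formal_charge_class == "cationic", 4.3,
              c("salt_bridge"), "anion-cation")
  if (min(d) < 2.8) {
    stop(sprintf("plant_complex: cross-chain atoms at %.2f A (< 2.8): would
  create close-contact records", min(d)))
  }
  # ring-cation geometry: the planted pi-cation pair must have at least one
  # ring detecting with margin (records are deduplicated per residue pair,
  # so additional rings of the same pair are harmless); no other pair may
  # come anywhere near the thresholds
  pi_margin_ok <- character(0)
  for (side in 1:2) {
    rings <- find_rings(detector_atoms(if (side == 1) rec else lig))
    other <- detector_atoms(if (side == 1) lig else rec)
    cats <- which(other$formal_charge_class == "cationic" & other$element == "N")
    for (rg in rings) {
      for (ci in cats) {
        v <- c(other$x[ci], other$y[ci], other$z[ci]) - rg$centroid
        dist_rc <- sqrt(sum(v^2))
        ang <- acos(pmin(1, abs(sum(v * rg$normal)) / dist_rc)) * 180 / pi
        rec_no <- if (side == 1) as.integer(sub(".*:", "", rg$key)) else
          other$resno[ci]
        lig_no <- if (side == 1) other$resno[ci] else
          as.integer(sub(".*:", "", rg$key))
        key <- paste(rec_no, lig_no)
        is_planted_pi <- !is.na(planted_kind[key]) &&
          planted_kind[key] == "pi_cation"
        if (is_planted_pi) {
          if (dist_rc <= 5.7 && ang <= 50) pi_margin_ok <- c(pi_margin_ok, key)
        } else if (dist_rc <= 6.3 && ang <= 70) {
          stop(sprintf(
            "plant_complex: ambiguous ring-cation geometry (pair %s, %.2f A, %.0f deg)",
            key, dist_rc, ang))
        }
      }
    }
  }
  want_pi <- names(planted_kind)[planted_kind == "pi_cation"]
  if (!all(want_pi %in% pi_margin_ok)) {
    stop("plant_complex: planted pi-cation lacks an in-margin ring")
  }

  # ---- ground truth ----
  contacts <- do.call(rbind, lapply(spec$planted, function(p) {
    data.frame(kind = p$kind, rec_resno = p$rec_resno, lig_resno = p$lig_resno,
               distance = p$distance, stringsAsFactors = FALSE)
  }))
  # a planted salt bridge at <= 3.5 A is also a donor-acceptor pair and is
  # reported by the hydrogen-bond detector
  for (p in spec$planted) {
    if (p$kind == "salt_bridge" && p$distance <= 3.5) {
      contacts <- rbind(contacts, data.frame(
        kind = "hbond", rec_resno = p$rec_resno, lig_resno = p$lig_resno,
        distance = p$distance, stringsAsFactors = FALSE))
    }
  }
  # RRCS ground truth: a cross-chain residue pair scores iff some atom pair
  # is inside the 4.63 A ramp support; require a 0.15 A guard band so the
  # expectation is unambiguous (recomputed here from raw coordinates only)
  rrcs_expected <- list()
  for (pk in planted_pairs) {
    nos <- as.integer(strsplit(pk, " ")[[1]])
    dd <- d[ra$resno == nos[1], la$resno == nos[2], drop = FALSE]
    mn <- min(dd)
    if (mn > 4.63 - 0.15 && mn < 4.63 + 0.15) {
      stop(sprintf("plant_complex: pair %s ambiguous for RRCS (min %.2f)", pk, mn))
    }
    if (mn < 4.63) {
      rrcs_expected[[length(rrcs_expected) + 1L]] <-
        data.frame(rec_resno = nos[1], lig_resno = nos[2])
    }
  }
  truth <- list(
    contacts = contacts,
    rrcs_pairs = do.call(rbind, rrcs_expected),
    interface_rec = unique(vapply(spec$planted, function(p) p$rec_resno,
                                  integer(1))),
    interface_lig = unique(vapply(spec$planted, function(p) p$lig_resno,
                                  integer(1))),
    pose = identity_pose(),
    spec = spec
  )
  list(receptor = rec, ligand = lig, truth = truth)
}

#' Jittered conformational ensemble of a Structure
#'
#' Emulates an NMR-style multi-model ensemble: per-atom Gaussian displacement
#' of scale \code{jitter} applied to side-chain atoms only (backbone N, CA,
#' C, O fixed), identical topology across models, deterministic per seed.
#'
#' @param base Structure
#' @param n_models number of models (>= 1)
#' @param jitter displacement scale, Angstrom (>= 0)
#' @param seed integer seed
#' @return list of Structures with model_id 1..n_models
#' @export
make_ensemble <- function(base, n_models, jitter = 0.3, seed = 1L) {
  stopifnot(n_models >= 1, jitter >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  side <- !(base$atoms$name %in% c("N", "CA", "C", "O")) & !base$atoms$is_hydrogen
  lapply(seq_len(n_models), function(i) {
    s <- base
    if (jitter > 0) {
      n <- sum(side)
      s$atoms$x[side] <- s$atoms$x[side] + stats::rnorm(n, 0, jitter)
      s$atoms$y[side] <- s$atoms$y[side] + stats::rnorm(n, 0, jitter)
      s$atoms$z[side] <- s$atoms$z[side] + stats::rnorm(n, 0, jitter)
    }
    s$model_id <- as.integer(i)
    s$provenance$model_index <- as.integer(i)
    s
  })
}

#' Graded rigid decoys of a planted pose
#'
#' Random rigid perturbations of the ligand's planted placement at linearly
#' increasing magnitudes, with the heavy-atom RMSD to the optimum recorded.
#'
#' @param receptor receptor Structure (unused geometrically; kept for
#'   interface symmetry and future clash filtering)
#' @param ligand ligand Structure in its planted placement
#' @param ground_truth truth list from \code{\link{plant_complex}}
#' @param n number of decoys
#' @param seed integer seed
#' @param max_translation,max_rotation magnitude of the largest decoy
#'   (Angstrom, degrees)
#' @return list of list(pose, rmsd)
#' @export
make_decoys <- function(receptor, ligand, ground_truth, n, seed = 1L,
                        max_translation = 8, max_rotation = 60) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    frac <- i / n
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    axis <- stats::rnorm(3)
    pose <- new_pose(
      quat_from_axis_angle(axis, frac * max_rotation * pi / 180),
      frac * max_translation * dir, model_id = ligand$model_id
    )
    placed <- apply_pose(ligand, pose)
    list(pose = pose, rmsd = ligand_rmsd(ligand, placed))
  })
}

#' Standard planted-pose recovery experiment
#'
#' Packages the docking configuration used to test pose recovery on the
#' standard fixture: a cubic box of the given half-width centred on the
#' planted ligand centroid.
#'
#' @param cx list from \code{\link{plant_complex}}
#' @param seed search seed
#' @param n_restarts restarts
#' @param half box half-width, Angstrom
#' @return SearchConfig
#' @export
recovery_config <- function(cx, seed = 1L, n_restarts = 64L, half = 12) {
  cen <- colMeans(coords(cx$ligand, heavy = TRUE))
  search_config(box_center = cen, box_half = rep(half, 3),
                n_restarts = n_restarts, seed = seed)
}
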