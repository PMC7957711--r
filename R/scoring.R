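# Five-term empirical inter-molecular scoring of a rigid ligand pose.
#
# The score acts on the surface distance d = |ri - rj| - (Ri + Rj) between
# heavy-atom pairs (Ri, Rj are scoring radii):
#   gauss1      exp(-(d / 0.5)^2)                 attractive, short range
#   gauss2      exp(-((d - 3) / 2)^2)             attractive, medium range
#   repulsion   d^2 for d < 0, else 0             steric clash penalty
#   hydrophobic linear ramp 1 -> 0 on d in [0.5, 1.5], hydrophobic C pairs only
#   hbond       linear ramp 1 -> 0 on d in [-0.7, 0], donor-acceptor pairs only
# Total = sum over inter-molecular heavy-atom pairs with CENTER distance <=
# cutoff (8 A) of sum_term weight_term * term(d). The protocol is rigid-body,
# so no torsion-count normalisation is applied (divisor 1) and totals are
# directly comparable across poses.

#' Scoring parameters for the empirical pose score
#'
#' Defaults are the published weights of the empirical scoring function used
#' by common docking codes for rigid rescoring; totals are conventionally
#' reported in kcal/mol.
#'
#' @param weights named numeric: gauss1, gauss2, repulsion, hydrophobic, hbond
#' @param cutoff center-distance cutoff in Angstrom
#' @param hydrophobic_ramp,hbond_ramp 2-vectors (full-value end, zero end) of
#'   the linear ramps, Angstrom of surface distance
#' @return ScoringParams object
#' @export
scoring_params <- function(weights = c(gauss1 = -0.035579, gauss2 = -0.005156,
                                       repulsion = 0.840245,
                                       hydrophobic = -0.035069,
                                       hbond = -0.587439),
                           cutoff = 8.0,
                           hydrophobic_ramp = c(0.5, 1.5),
                           hbond_ramp = c(-0.7, 0.0)) {
  stopifnot(cutoff > 0,
            hydrophobic_ramp[1] < hydrophobic_ramp[2],
            hbond_ramp[1] < hbond_ramp[2])
  req <- c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond")
  if (!all(req %in% names(weights))) {
    stop("weights must name: ", paste(req, collapse = ", "))
  }
  structure(list(weights = weights[req], cutoff = cutoff,
                 hydrophobic_ramp = hydrophobic_ramp, hbond_ramp = hbond_ramp),
            class = "ScoringParams")
}

#' Surface distance between two typed atoms
#'
#' Center distance minus the sum of the scoring radii; negative when the
#' atomic spheres interpenetrate.
#' @param atom_i,atom_j one-row data.frames from a typed Structure's atoms
#' @return distance in Angstrom
#' @export
surface_distance <- function(atom_i, atom_j) {
  if (is.na(atom_i$xs_radius) || is.na(atom_j$xs_radius)) {
    stop("surface_distance: untyped atom")
  }
  d <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
              (atom_i$z - atom_j$z)^2)
  d - (atom_i$xs_radius + atom_j$xs_radius)
}

ramp_down <- function(d, lo, hi) {
  # 1 below lo, linear to 0 at hi
  v <- (hi - d) / (hi - lo)
  pmin(1, pmax(0, v))
}

#' Evaluate the five unweighted pair terms
#'
#' Vectorised over \code{d}. The hydrophobic and hbond terms are zero unless
#' the pair qualifies (\code{both_hydrophobic} / \code{donor_acceptor}).
#'
#' @param d surface distance(s), Angstrom
#' @param both_hydrophobic logical, pair of hydrophobic carbons
#' @param donor_acceptor logical, donor-acceptor pair (either direction)
#' @param params ScoringParams
#' @return matrix with columns gauss1, gauss2, repulsion, hydrophobic, hbond
#' @export
pair_terms <- function(d, both_hydrophobic = FALSE, donor_acceptor = FALSE,
                       params = scoring_params()) {
  n <- length(d)
  both_hydrophobic <- rep_len(both_hydrophobic, n)
  donor_acceptor <- rep_len(donor_acceptor, n)
  cbind(
    gauss1 = exp(-(d / 0.5)^2),
    gauss2 = exp(-((d - 3) / 2)^2),
    repulsion = ifelse(d < 0, d^2, 0),
    hydrophobic = ifelse(both_hydrophobic,
                         ramp_down(d, params$hydrophobic_ramp[1],
                                   params$hydrophobic_ramp[2]), 0),
    hbond = ifelse(donor_acceptor,
                   ramp_down(d, params$hbond_ramp[1], params$hbond_ramp[2]), 0)
  )
}

# Precompute everything reusable across poses of one receptor/ligand pair.
# Returns a context used by score_with_context() in the docking inner loop.
score_context <- function(receptor, ligand, params) {
  rm_ <- scoring_atom_mask(receptor)
  lm_ <- scoring_atom_mask(ligand)
  ra <- receptor$atoms[rm_, , drop = FALSE]
  la <- ligand$atoms[lm_, , drop = FALSE]
  if (!nrow(ra) || !nrow(la)) stop("score_complex: empty molecule")
  list(
    params = params,
    r_xyz = as.matrix(ra[, c("x", "y", "z")]),
    l_xyz = as.matrix(la[, c("x", "y", "z")]),
    r_rad = ra$xs_radius, l_rad = la$xs_radius,
    r_hyd = ra$is_hydrophobic, l_hyd = la$is_hydrophobic,
    r_don = ra$is_donor, l_don = la$is_donor,
    r_acc = ra$is_acceptor, l_acc = la$is_acceptor,
    r_key = paste0(ra$chain, ":", ra$resno, ra$ins),
    l_key = paste0(la$chain, ":", la$resno, la$ins)
  )
}

# Core evaluation; l_xyz overrides the ligand coordinates (docking moves).
# Returns list(total, per_term, pairs = data.frame(i, j, contrib)) where i/j
# index the context's receptor/ligand scoring atoms.
score_with_context <- function(ctx, l_xyz = NULL, want_pairs = TRUE) {
  if (is.null(l_xyz)) l_xyz <- ctx$l_xyz
  w <- ctx$params$weights
  cutoff2 <- ctx$params$cutoff^2
  d2 <- cross_dist2(ctx$r_xyz, l_xyz)
  hit <- which(d2 <= cutoff2)
  if (!length(hit)) {
    return(list(total = 0, per_term = c(gauss1 = 0, gauss2 = 0, repulsion = 0,
                                        hydrophobic = 0, hbond = 0),
                pairs = if (want_pairs)
                  data.frame(i = integer(0), j = integer(0),
                             contrib = numeric(0)) else NULL))
  }
  nr <- nrow(ctx$r_xyz)
  i <- ((hit - 1L) %% nr) + 1L
  j <- ((hit - 1L) %/% nr) + 1L
  d <- sqrt(d2[hit]) - (ctx$r_rad[i] + ctx$l_rad[j])
  terms <- pair_terms(
    d,
    both_hydrophobic = ctx$r_hyd[i] & ctx$l_hyd[j],
    donor_acceptor = (ctx$r_don[i] & ctx$l_acc[j]) |
      (ctx$r_acc[i] & ctx$l_don[j]),
    params = ctx$params
  )
  contrib <- as.vector(terms %*% w)
  list(
    total = sum(contrib),
    per_term = colSums(terms),
    pairs = if (want_pairs) data.frame(i = i, j = j, contrib = contrib) else NULL
  )
}

#' Score a rigid receptor-ligand complex
#'
#' Sums the five weighted empirical terms over all inter-molecular heavy-atom
#' pairs within the center-distance cutoff and attributes every pair
#' contribution to its receptor and ligand residues. Water and metal atoms
#' are excluded.
#'
#' @param receptor,ligand typed Structures sharing one coordinate frame
#' @param params ScoringParams
#' @return ScoreBreakdown: list with \code{total} (weighted sum, kcal/mol
#'   scale), \code{per_term} (unweighted term sums), \code{per_receptor_residue}
#'   and \code{per_ligand_residue} (named contribution vectors summing to the
#'   total), \code{n_pairs}, and residue id tables
#' @export
score_complex <- function(receptor, ligand, params = scoring_params()) {
  require_typed(receptor, "score_complex")
  require_typed(ligand, "score_complex")
  ctx <- score_context(receptor, ligand, params)
  ev <- score_with_context(ctx)
  pr <- ev$pairs
  per_rec <- if (nrow(pr)) {
    v <- rowsum(pr$contrib, ctx$r_key[pr$i])
    stats::setNames(as.vector(v), rownames(v))
  } else stats::setNames(numeric(0), character(0))
  per_lig <- if (nrow(pr)) {
    v <- rowsum(pr$contrib, ctx$l_key[pr$j])
    stats::setNames(as.vector(v), rownames(v))
  } else stats::setNames(numeric(0), character(0))
  structure(list(
    total = ev$total,
    per_term = ev$per_term,
    per_receptor_residue = per_rec,
    per_ligand_residue = per_lig,
    n_pairs = nrow(pr),
    receptor_residues = residue_table(receptor),
    ligand_residues = residue_table(ligand),
    params = params
  ), class = "ScoreBreakdown")
}

#' @export
print.ScoreBreakdown <- function(x, ...) {
  cat(sprintf("ScoreBreakdown: total %.4f over %d atom pairs\n", x$total, x$n_pairs))
  cat("  unweighted terms:",
      paste(sprintf("%s=%.3f", names(x$per_term), x$per_term), collapse = " "), "\n")
  invisible(x)
}

#' Per-residue decomposition of a complex score
#'
#' Orders receptor residues by their contribution to the total score, most
#' stabilising (most negative) first; optionally restricted to a region.
#'
#' @param b ScoreBreakdown from \code{\link{score_complex}}
#' @param region optional RegionSpec resolved against the receptor residues
#' @param side "receptor" (default) or "ligand"
#' @return data.frame(key, resname, contribution) sorted ascending
#' @export
decompose_by_residue <- function(b, region = NULL, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  contrib <- if (side == "receptor") b$per_receptor_residue else b$per_ligand_residue
  rt <- if (side == "receptor") b$receptor_residues else b$ligand_residues
  df <- data.frame(key = names(contrib), contribution = as.vector(contrib),
                   stringsAsFactors = FALSE)
  df$resname <- rt$resname[match(df$key, rt$key)]
  if (!is.null(region)) {
    keep <- rt$key[region_residue_mask(rt, region)]
    df <- df[df$key %in% keep, , drop = FALSE]
  }
  df <- df[order(df$contribution), c("key", "resname", "contribution")]
  rownames(df) <- NULL
  df
}
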