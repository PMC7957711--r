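# Seeded rigid-body pose search under the empirical score.
#
# A Pose is a rigid transform of the ligand about its ORIGINAL heavy-atom
# centroid c0:  x' = R(q) (x - c0) + c0 + t.
# The search is multistart Metropolis Monte Carlo over the 6 rigid degrees of
# freedom: each restart draws a uniform random orientation (Shoemake) and a
# uniform centroid position inside the search box, then anneals with normal
# proposals (base sigma 0.5 A translation / 5 deg rotation, both scaled with
# the square root of the cooling factor so late moves are fine-grained) under
# a geometric temperature schedule. Restarts are pooled, deduplicated by
# ligand RMSD and returned sorted by score; ties break on restart index, so
# output is bit-reproducible for a fixed seed.

#' Search configuration for rigid docking
#'
#' @param box_center length-3 center of the translation box, Angstrom
#' @param box_half length-3 half-widths of the box, Angstrom
#' @param n_restarts number of independent Monte-Carlo restarts
#' @param steps annealing steps per restart
#' @param t_init,t_final initial/final temperature of the geometric schedule
#'   (score units)
#' @param sigma_translation,sigma_rotation base proposal scales (Angstrom,
#'   degrees)
#' @param seed integer RNG seed
#' @param keep_top number of poses returned
#' @param dedup_rmsd RMSD threshold (Angstrom) for pose deduplication
#' @return SearchConfig object
#' @export
search_config <- function(box_center, box_half, n_restarts = 16L,
                          steps = 500L, t_init = 0.5, t_final = 0.02,
                          sigma_translation = 0.5, sigma_rotation = 5,
                          seed = 1L, keep_top = 20L, dedup_rmsd = 2.0) {
  if (n_restarts < 1) stop("search_config: n_restarts must be >= 1")
  if (keep_top < 1) stop("search_config: keep_top must be >= 1")
  if (steps < 1) stop("search_config: steps must be >= 1")
  if (any(box_half <= 0)) stop("search_config: box half-widths must be positive")
  stopifnot(length(box_center) == 3, length(box_half) == 3,
            t_init > 0, t_final > 0, t_final <= t_init)
  structure(list(box_center = as.numeric(box_center),
                 box_half = as.numeric(box_half),
                 n_restarts = as.integer(n_restarts), steps = as.integer(steps),
                 t_init = t_init, t_final = t_final,
                 sigma_translation = sigma_translation,
                 sigma_rotation = sigma_rotation,
                 seed = as.integer(seed), keep_top = as.integer(keep_top),
                 dedup_rmsd = dedup_rmsd),
            class = "SearchConfig")
}

new_pose <- function(q, t, model_id = 1L, rank = NA_integer_) {
  structure(list(rotation = quat_normalize(q), translation = as.numeric(t),
                 model_id = as.integer(model_id), rank = rank),
            class = "Pose")
}

#' Identity pose
#' @param model_id ligand model id carried by the pose
#' @return Pose leaving the ligand where it is
#' @export
identity_pose <- function(model_id = 1L) new_pose(c(1, 0, 0, 0), c(0, 0, 0), model_id)

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("Pose (model %d, rank %s): q=[%.3f %.3f %.3f %.3f] t=[%.2f %.2f %.2f]\n",
              x$model_id, as.character(x$rank),
              x$rotation[1], x$rotation[2], x$rotation[3], x$rotation[4],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Transform an n x 3 coordinate matrix by a pose, about centroid c0.
pose_transform <- function(xyz, pose, c0) {
  R <- quat_to_matrix(pose$rotation)
  sweep(tcrossprod(sweep(xyz, 2, c0), R), 2, c0 + pose$translation, "+")
}

#' Apply a Pose to a ligand Structure
#'
#' The rotation acts about the ligand's heavy-atom centroid in its current
#' placement; the translation then shifts the centroid.
#' @param ligand Structure
#' @param pose Pose
#' @return transformed Structure
#' @export
apply_pose <- function(ligand, pose) {
  xyz <- coords(ligand)
  hxyz <- coords(ligand, heavy = TRUE)
  c0 <- colMeans(hxyz)
  set_coords(ligand, pose_transform(xyz, pose, c0))
}

# squared-RMSD between cached heavy-atom coordinate matrices
rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Greedy best-first pose clustering
#'
#' Walks the pose list in order and keeps a pose iff its ligand RMSD to every
#' already-kept pose exceeds \code{dedup_rmsd}. Poses must carry cached
#' heavy-atom coordinates (as produced by \code{\link{dock_rigid}}) or a
#' ligand must be supplied.
#'
#' @param poses list of Pose objects (ordered best first)
#' @param dedup_rmsd RMSD threshold, Angstrom
#' @param ligand optional ligand Structure used to realise coordinates
#' @return filtered list of poses
#' @export
cluster_poses <- function(poses, dedup_rmsd, ligand = NULL) {
  if (!length(poses)) return(poses)
  get_xyz <- function(p) {
    if (!is.null(p$coords)) return(p$coords)
    if (is.null(ligand)) stop("cluster_poses: poses carry no coordinates; supply ligand")
    xyz <- coords(ligand, heavy = TRUE)
    pose_transform(xyz, p, colMeans(xyz))
  }
  kept <- list()
  kept_xyz <- list()
  for (p in poses) {
    x <- get_xyz(p)
    dup <- FALSE
    for (kx in kept_xyz) {
      if (rmsd_between(x, kx) <= dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- p
      kept_xyz[[length(kept_xyz) + 1L]] <- x
    }
  }
  kept
}

#' Rigid-body docking by multistart Monte-Carlo annealing
#'
#' Runs \code{cfg$n_restarts} independent annealing trajectories from uniform
#' random orientations/positions in the search box, pools the best pose of
#' each restart, deduplicates at \code{cfg$dedup_rmsd} and returns the top
#' \code{cfg$keep_top} poses sorted ascending by total score (ties: lower
#' restart index first). Bit-reproducible for a fixed seed.
#'
#' @param receptor,ligand typed Structures
#' @param cfg SearchConfig
#' @param params ScoringParams
#' @return list of entries \code{list(pose, breakdown)}, best first; each pose
#'   carries cached heavy-atom \code{coords} and the originating
#'   \code{restart}
#' @export
dock_rigid <- function(receptor, ligand, cfg, params = scoring_params()) {
  require_typed(receptor, "dock_rigid")
  require_typed(ligand, "dock_rigid")
  stopifnot(inherits(cfg, "SearchConfig"))

  hxyz <- coords(ligand, heavy = TRUE)
  c0 <- colMeans(hxyz)
  # the box confines the ligand CENTROID (the molecule may extend beyond it,
  # as in standard docking practice); guard only against degenerate boxes
  # smaller than the ligand itself
  rg <- sqrt(mean(rowSums(sweep(hxyz, 2, c0)^2)))
  if (sqrt(sum((2 * cfg$box_half)^2)) < rg / 2) {
    stop("dock_rigid: box too small to contain the ligand")
  }
  if (any(abs(c0 - cfg$box_center) > cfg$box_half + 1e-9)) {
    stop("dock_rigid: box does not enclose the ligand start")
  }

  ctx <- score_context(receptor, ligand, params)
  # ligand scoring-atom coordinates in the untransformed frame
  l0 <- ctx$l_xyz
  heavy0 <- hxyz

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  cool <- if (cfg$steps > 1) {
    (cfg$t_final / cfg$t_init)^(1 / (cfg$steps - 1))
  } else 1
  results <- vector("list", cfg$n_restarts)
  for (k in seq_len(cfg$n_restarts)) {
    q <- quat_random()
    t_vec <- cfg$box_center + stats::runif(3, -cfg$box_half, cfg$box_half) - c0
    cur_xyz <- pose_transform(l0, list(rotation = q, translation = t_vec), c0)
    cur_score <- score_with_context(ctx, cur_xyz, want_pairs = FALSE)$total
    best <- list(q = q, t = t_vec, score = cur_score)
    temp <- cfg$t_init
    for (step in seq_len(cfg$steps)) {
      scale <- max(sqrt(temp / cfg$t_init), 0.15)
      dq <- quat_from_axis_angle(
        stats::rnorm(3),
        stats::rnorm(1, 0, cfg$sigma_rotation * scale) * pi / 180
      )
      q_new <- quat_normalize(quat_multiply(dq, q))
      t_new <- t_vec + stats::rnorm(3, 0, cfg$sigma_translation * scale)
      # keep the centroid inside the box
      cen <- c0 + t_new
      cen <- pmin(pmax(cen, cfg$box_center - cfg$box_half),
                  cfg$box_center + cfg$box_half)
      t_new <- cen - c0
      new_xyz <- pose_transform(l0, list(rotation = q_new, translation = t_new), c0)
      new_score <- score_with_context(ctx, new_xyz, want_pairs = FALSE)$total
      if (new_score <= cur_score ||
          stats::runif(1) < exp((cur_score - new_score) / temp)) {
        q <- q_new; t_vec <- t_new; cur_score <- new_score
        if (cur_score < best$score) best <- list(q = q, t = t_vec, score = cur_score)
      }
      temp <- temp * cool
    }
    results[[k]] <- list(q = best$q, t = best$t, score = best$score, restart = k)
  }

  ord <- order(vapply(results, `[[`, numeric(1), "score"),
               vapply(results, `[[`, integer(1), "restart"))
  poses <- lapply(results[ord], function(r) {
    p <- new_pose(r$q, r$t, model_id = ligand$model_id)
    p$restart <- r$restart
    p$score <- r$score
    p$coords <- pose_transform(heavy0, p, c0)
    p
  })
  poses <- cluster_poses(poses, cfg$dedup_rmsd)
  poses <- poses[seq_len(min(cfg$keep_top, length(poses)))]

  lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    p$rank <- i
    placed <- apply_pose(ligand, p)
    list(pose = p, breakdown = score_complex(receptor, placed, params))
  })
}

#' Write ranked docking poses as a multi-MODEL PDB plus a TSV score table
#'
#' @param results list returned by \code{\link{dock_rigid}}
#' @param ligand the ligand Structure the poses refer to
#' @param pdb_path output PDB path (one MODEL per pose)
#' @param tsv_path output TSV path (rank, total, per-term columns)
#' @return invisibly, a data.frame of the score table
#' @export
write_pose_set <- function(results, ligand, pdb_path, tsv_path = NULL) {
  placed <- lapply(results, function(r) apply_pose(ligand, r$pose))
  write_pdb(placed, pdb_path)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(rank = r$pose$rank, total = r$breakdown$total,
               t(r$breakdown$per_term))
  }))
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(tab)
}
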