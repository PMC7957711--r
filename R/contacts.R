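# Residue-residue contact scores (RRCS) and geometric interaction detectors.
#
# RRCS of a residue pair is the sum over all inter-residue heavy-atom pairs of
# a piecewise-linear distance ramp:
#   c(d) = 1                  for d <= 3.23 A
#   c(d) = (4.63 - d) / 1.4   for 3.23 < d < 4.63 A
#   c(d) = 0                  otherwise
# For residues of the same chain fewer than 5 positions apart the backbone
# atoms N, CA, C, O are excluded (the sequence-adjacency rule); inter-chain
# pairs, the only ones produced by rrcs_matrix(), never trigger it.
#
# All detectors are heavy-atom based and inter-chain only. Default geometric
# criteria (configurable via contact_params()):
#   hydrogen bond   donor heavy atom to acceptor heavy atom <= 3.5 A
#   salt bridge     cationic N (Lys NZ; Arg NE/NH1/NH2) to anionic O
#                   (Asp OD1/OD2; Glu OE1/OE2; OXT) <= 4.0 A
#   pi-cation       aromatic ring centroid (Phe/Tyr 6-ring, Trp both rings,
#                   His imidazole) to cationic N <= 6.0 A and angle between
#                   ring normal and centroid->cation vector <= 60 deg
#   hydrophobic     hydrophobic carbon pairs <= 4.5 A, one record per residue
#                   pair with the pair count
#   close contact   any heavy-atom pair < 2.5 A
# A small tolerance (1e-9) keeps planted boundary geometries deterministic.

RRCS_PLATEAU <- 3.23
RRCS_ZERO <- 4.63

#' Geometric thresholds for the interaction detectors
#' @param hbond_max donor-acceptor heavy-atom distance, Angstrom
#' @param salt_bridge_max cation-anion distance, Angstrom
#' @param pi_cation_max ring-centroid to cation distance, Angstrom
#' @param pi_cation_angle_max ring-normal angle, degrees
#' @param hydrophobic_max carbon-carbon distance, Angstrom
#' @param close_contact_max close-contact distance, Angstrom
#' @return ContactParams object
#' @export
contact_params <- function(hbond_max = 3.5, salt_bridge_max = 4.0,
                           pi_cation_max = 6.0, pi_cation_angle_max = 60,
                           hydrophobic_max = 4.5, close_contact_max = 2.5) {
  structure(list(hbond_max = hbond_max, salt_bridge_max = salt_bridge_max,
                 pi_cation_max = pi_cation_max,
                 pi_cation_angle_max = pi_cation_angle_max,
                 hydrophobic_max = hydrophobic_max,
                 close_contact_max = close_contact_max),
            class = "ContactParams")
}

EPS_GEOM <- 1e-9

rrcs_ramp <- function(d) {
  ifelse(d <= RRCS_PLATEAU, 1,
         ifelse(d < RRCS_ZERO, (RRCS_ZERO - d) / (RRCS_ZERO - RRCS_PLATEAU), 0))
}

#' RRCS of one residue pair
#'
#' @param res_i,res_j atom data.frames (rows of a typed Structure's atoms
#'   belonging to one residue each)
#' @param seq_adjacent_rule apply the same-chain |delta resno| < 5 backbone
#'   exclusion
#' @return nonnegative contact score
#' @export
rrcs_pair <- function(res_i, res_j, seq_adjacent_rule = FALSE) {
  ai <- res_i[!res_i$is_hydrogen, , drop = FALSE]
  aj <- res_j[!res_j$is_hydrogen, , drop = FALSE]
  if (seq_adjacent_rule &&
      ai$chain[1] == aj$chain[1] && abs(ai$resno[1] - aj$resno[1]) < 5) {
    ai <- ai[!(ai$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
    aj <- aj[!(aj$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  }
  if (!nrow(ai) || !nrow(aj)) return(0)
  d <- sqrt(cross_dist2(as.matrix(ai[, c("x", "y", "z")]),
                        as.matrix(aj[, c("x", "y", "z")])))
  sum(rrcs_ramp(d))
}

#' Sparse residue-residue contact score matrix between two molecules
#'
#' Scores every inter-chain residue pair with any heavy-atom distance below
#' the 4.63 A ramp support; pairs with no such atoms are absent from the
#' result.
#'
#' @param ligand,receptor typed Structures
#' @return RRCSMatrix: list with \code{entries}
#'   data.frame(lig_key, rec_key, rec_resname, rec_is_glycan, score) and
#'   residue tables of both molecules
#' @export
rrcs_matrix <- function(ligand, receptor) {
  require_typed(ligand, "rrcs_matrix")
  require_typed(receptor, "rrcs_matrix")
  la <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  ra <- receptor$atoms[!receptor$atoms$is_hydrogen, , drop = FALSE]
  lrt <- residue_table(ligand)
  rrt <- residue_table(receptor)
  entries <- data.frame(lig_key = character(0), rec_key = character(0),
                        rec_resname = character(0), rec_is_glycan = logical(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(la) && nrow(ra)) {
    d <- sqrt(cross_dist2(as.matrix(la[, c("x", "y", "z")]),
                          as.matrix(ra[, c("x", "y", "z")])))
    lkey <- paste0(la$chain, ":", la$resno, la$ins)
    rkey <- paste0(ra$chain, ":", ra$resno, ra$ins)
    hit <- which(d < RRCS_ZERO, arr.ind = TRUE)
    if (nrow(hit)) {
      contrib <- rrcs_ramp(d[hit])
      pair <- paste(lkey[hit[, 1]], rkey[hit[, 2]], sep = "\r")
      agg <- rowsum(contrib, pair)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      entries <- data.frame(
        lig_key = vapply(parts, `[`, character(1), 1),
        rec_key = vapply(parts, `[`, character(1), 2),
        score = as.vector(agg),
        stringsAsFactors = FALSE
      )
      m <- match(entries$rec_key, rrt$key)
      entries$rec_resname <- rrt$resname[m]
      entries$rec_is_glycan <- rrt$is_glycan[m]
      entries <- entries[order(match(entries$lig_key, lrt$key),
                               match(entries$rec_key, rrt$key)),
                         c("lig_key", "rec_key", "rec_resname",
                           "rec_is_glycan", "score")]
      rownames(entries) <- NULL
    }
  }
  structure(list(entries = entries, ligand_residues = lrt,
                 receptor_residues = rrt),
            class = "RRCSMatrix")
}

#' @export
print.RRCSMatrix <- function(x, ...) {
  cat(sprintf("RRCSMatrix: %d nonzero residue pairs, grand total %.2f\n",
              nrow(x$entries), sum(x$entries$score)))
  invisible(x)
}

#' Aggregate an RRCS matrix over a receptor region and/or partition
#'
#' @param m RRCSMatrix
#' @param receptor_region optional RegionSpec over receptor residues
#' @param partition "all", "AA" (non-glycan receptor residues) or "glycan"
#' @return scalar total score
#' @export
rrcs_aggregate <- function(m, receptor_region = NULL,
                           partition = c("all", "AA", "glycan")) {
  partition <- match.arg(partition)
  e <- m$entries
  keep <- rep(TRUE, nrow(e))
  if (!is.null(receptor_region)) {
    rkeys <- m$receptor_residues$key[
      region_residue_mask(m$receptor_residues, receptor_region)]
    if (!length(rkeys)) stop("rrcs_aggregate: region resolves to no residues")
    keep <- keep & e$rec_key %in% rkeys
  }
  if (partition == "AA") keep <- keep & !e$rec_is_glycan
  if (partition == "glycan") keep <- keep & e$rec_is_glycan
  sum(e$score[keep])
}

# ---- detectors -------------------------------------------------------------

# shared scaffolding: typed heavy atoms of both molecules plus residue keys
detector_atoms <- function(s) {
  a <- s$atoms[scoring_atom_mask(s), , drop = FALSE]
  a$key <- paste0(a$chain, ":", a$resno, a$ins)
  a$side_class <- ifelse(a$is_glycan, "s", ifelse(a$is_backbone, "b", "s"))
  a
}

empty_contacts <- function() {
  data.frame(kind = character(0), lig_key = character(0), rec_key = character(0),
             lig_res = character(0), rec_res = character(0),
             lig_atom = character(0), rec_atom = character(0),
             class = character(0), distance = numeric(0), angle = numeric(0),
             n_atom_pairs = integer(0), stringsAsFactors = FALSE)
}

contact_frame <- function(kind, la, ra, li, ri, dist, angle = NA_real_,
                          class = NULL, n_atom_pairs = 1L) {
  if (!length(li)) return(empty_contacts())
  if (is.null(class)) class <- paste0(ra$side_class[ri], la$side_class[li])
  data.frame(
    kind = kind,
    lig_key = la$key[li], rec_key = ra$key[ri],
    lig_res = paste(la$resname[li], la$resno[li]),
    rec_res = paste(ra$resname[ri], ra$resno[ri]),
    lig_atom = la$name[li], rec_atom = ra$name[ri],
    class = class, distance = dist, angle = angle,
    n_atom_pairs = as.integer(n_atom_pairs),
    stringsAsFactors = FALSE
  )
}

#' Detect inter-molecular hydrogen bonds (heavy-atom criterion)
#'
#' Reports donor-acceptor heavy-atom pairs across the two molecules within
#' the distance threshold, in both donor directions. The class string is the
#' donor side-chain/backbone letter followed by the acceptor letter
#' (s = side chain, b = backbone; glycan atoms count as side chain).
#'
#' @param ligand,receptor typed Structures
#' @param params ContactParams
#' @return data.frame of ContactRecords
#' @export
detect_hbonds <- function(ligand, receptor, params = contact_params()) {
  require_typed(ligand, "detect_hbonds")
  require_typed(receptor, "detect_hbonds")
  la <- detector_atoms(ligand)
  ra <- detector_atoms(receptor)
  out <- list()
  d <- sqrt(cross_dist2(as.matrix(la[, c("x", "y", "z")]),
                        as.matrix(ra[, c("x", "y", "z")])))
  # ligand donor -> receptor acceptor
  hit <- which(outer(la$is_donor, ra$is_acceptor, "&") &
                 d <= params$hbond_max + EPS_GEOM, arr.ind = TRUE)
  if (nrow(hit)) {
    out[[1]] <- contact_frame("hbond", la, ra, hit[, 1], hit[, 2], d[hit],
                              class = paste0(la$side_class[hit[, 1]],
                                             ra$side_class[hit[, 2]]))
  }
  # receptor donor -> ligand acceptor
  hit <- which(outer(la$is_acceptor, ra$is_donor, "&") &
                 d <= params$hbond_max + EPS_GEOM, arr.ind = TRUE)
  if (nrow(hit)) {
    out[[2]] <- contact_frame("hbond", la, ra, hit[, 1], hit[, 2], d[hit],
                              class = paste0(ra$side_class[hit[, 2]],
                                             la$side_class[hit[, 1]]))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_contacts())
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Detect inter-molecular salt bridges
#'
#' Cationic nitrogens versus anionic oxygens within the threshold; one record
#' per residue pair carrying the minimal distance.
#' @inheritParams detect_hbonds
#' @return data.frame of ContactRecords
#' @export
detect_salt_bridges <- function(ligand, receptor, params = contact_params()) {
  require_typed(ligand, "detect_salt_bridges")
  require_typed(receptor, "detect_salt_bridges")
  la <- detector_atoms(ligand)
  ra <- detector_atoms(receptor)
  pick <- function(a) list(
    cat = which(a$formal_charge_class == "cationic" & a$element == "N"),
    ani = which(a$formal_charge_class == "anionic" & a$element == "O")
  )
  lp <- pick(la); rp <- pick(ra)
  rows <- list()
  add_pairs <- function(li, ri) {
    if (!length(li) || !length(ri)) return(NULL)
    d <- sqrt(cross_dist2(as.matrix(la[li, c("x", "y", "z"), drop = FALSE]),
                          as.matrix(ra[ri, c("x", "y", "z"), drop = FALSE])))
    hit <- which(d <= params$salt_bridge_max + EPS_GEOM, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    contact_frame("salt_bridge", la, ra, li[hit[, 1]], ri[hit[, 2]], d[hit],
                  class = "ss")
  }
  rows[[1]] <- add_pairs(lp$cat, rp$ani)
  rows[[2]] <- add_pairs(lp$ani, rp$cat)
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res)) return(empty_contacts())
  # minimal-distance record per residue pair
  pair <- paste(res$lig_key, res$rec_key, sep = "\r")
  res <- res[order(pair, res$distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$lig_key, res$rec_key, sep = "\r")), , drop = FALSE]
  rownames(res) <- NULL
  res
}

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

# Enumerate complete aromatic rings of one molecule: list of
# list(key, res, centroid, normal)
find_rings <- function(a) {
  rings <- list()
  for (key in unique(a$key[a$resname %in% names(AROMATIC_RINGS)])) {
    res_atoms <- a[a$key == key, , drop = FALSE]
    for (ring_names in AROMATIC_RINGS[[res_atoms$resname[1]]]) {
      m <- match(ring_names, res_atoms$name)
      if (anyNA(m)) next
      xyz <- as.matrix(res_atoms[m, c("x", "y", "z")])
      cen <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, cen))
      rings[[length(rings) + 1L]] <- list(
        key = key, res = paste(res_atoms$resname[1], res_atoms$resno[1]),
        centroid = cen, normal = sv$v[, 3]
      )
    }
  }
  rings
}

#' Detect inter-molecular pi-cation interactions
#'
#' An aromatic ring (Phe/Tyr phenyl, Trp pyrrole and benzene rings, His
#' imidazole) on one molecule and a cationic nitrogen on the other, with the
#' centroid-cation distance and ring-normal angle within thresholds.
#' @inheritParams detect_hbonds
#' @return data.frame of ContactRecords (angle in degrees)
#' @export
detect_pi_cation <- function(ligand, receptor, params = contact_params()) {
  require_typed(ligand, "detect_pi_cation")
  require_typed(receptor, "detect_pi_cation")
  la <- detector_atoms(ligand)
  ra <- detector_atoms(receptor)
  rows <- list()
  scan <- function(ring_atoms, cation_atoms, ring_is_ligand) {
    rings <- find_rings(ring_atoms)
    cats <- which(cation_atoms$formal_charge_class == "cationic" &
                    cation_atoms$element == "N")
    for (rg in rings) {
      for (ci in cats) {
        v <- c(cation_atoms$x[ci], cation_atoms$y[ci], cation_atoms$z[ci]) -
          rg$centroid
        dist <- sqrt(sum(v^2))
        if (dist > params$pi_cation_max + EPS_GEOM) next
        cosang <- abs(sum(v * rg$normal)) / dist
        ang <- acos(pmin(1, cosang)) * 180 / pi
        if (ang > params$pi_cation_angle_max + EPS_GEOM) next
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "pi_cation",
          lig_key = if (ring_is_ligand) rg$key else cation_atoms$key[ci],
          rec_key = if (ring_is_ligand) cation_atoms$key[ci] else rg$key,
          lig_res = if (ring_is_ligand) rg$res else
            paste(cation_atoms$resname[ci], cation_atoms$resno[ci]),
          rec_res = if (ring_is_ligand)
            paste(cation_atoms$resname[ci], cation_atoms$resno[ci]) else rg$res,
          lig_atom = if (ring_is_ligand) "ring" else cation_atoms$name[ci],
          rec_atom = if (ring_is_ligand) cation_atoms$name[ci] else "ring",
          class = "ss", distance = dist, angle = ang, n_atom_pairs = 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  scan(la, ra, ring_is_ligand = TRUE)
  scan(ra, la, ring_is_ligand = FALSE)
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty_contacts())
  # one record per (residue pair, ring system): keep closest
  pair <- paste(res$lig_key, res$rec_key, sep = "\r")
  res <- res[order(pair, res$distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$lig_key, res$rec_key, sep = "\r")), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect inter-molecular hydrophobic contacts
#'
#' Pairs of hydrophobic carbons across the two molecules within the distance
#' threshold, aggregated to one record per residue pair with the count of
#' qualifying atom pairs and the minimal distance.
#' @inheritParams detect_hbonds
#' @return data.frame of ContactRecords
#' @export
detect_hydrophobic <- function(ligand, receptor, params = contact_params()) {
  require_typed(ligand, "detect_hydrophobic")
  require_typed(receptor, "detect_hydrophobic")
  la <- detector_atoms(ligand)
  ra <- detector_atoms(receptor)
  li <- which(la$is_hydrophobic)
  ri <- which(ra$is_hydrophobic)
  if (!length(li) || !length(ri)) return(empty_contacts())
  d <- sqrt(cross_dist2(as.matrix(la[li, c("x", "y", "z"), drop = FALSE]),
                        as.matrix(ra[ri, c("x", "y", "z"), drop = FALSE])))
  hit <- which(d <= params$hydrophobic_max + EPS_GEOM, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_contacts())
  res <- contact_frame("hydrophobic", la, ra, li[hit[, 1]], ri[hit[, 2]],
                       d[hit], class = "ss")
  pair <- paste(res$lig_key, res$rec_key, sep = "\r")
  counts <- table(pair)
  res <- res[order(pair, res$distance), , drop = FALSE]
  keep <- !duplicated(paste(res$lig_key, res$rec_key, sep = "\r"))
  res <- res[keep, , drop = FALSE]
  res$n_atom_pairs <- as.integer(counts[paste(res$lig_key, res$rec_key,
                                              sep = "\r")])
  rownames(res) <- NULL
  res
}

#' Residue pairs in close contact
#'
#' Inter-chain residue pairs with any heavy-atom distance below the cutoff
#' (default 2.5 A), flagging possible clashes or very tight polar contacts.
#' @inheritParams detect_hbonds
#' @param cutoff distance cutoff, Angstrom
#' @return data.frame(lig_key, rec_key, lig_res, rec_res, min_distance)
#' @export
close_contact_residues <- function(ligand, receptor, cutoff = 2.5) {
  if (cutoff <= 0) stop("close_contact_residues: cutoff must be positive")
  require_typed(ligand, "close_contact_residues")
  require_typed(receptor, "close_contact_residues")
  la <- detector_atoms(ligand)
  ra <- detector_atoms(receptor)
  d <- sqrt(cross_dist2(as.matrix(la[, c("x", "y", "z")]),
                        as.matrix(ra[, c("x", "y", "z")])))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(lig_key = character(0), rec_key = character(0),
                      lig_res = character(0), rec_res = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    lig_key = la$key[hit[, 1]], rec_key = ra$key[hit[, 2]],
    lig_res = paste(la$resname[hit[, 1]], la$resno[hit[, 1]]),
    rec_res = paste(ra$resname[hit[, 2]], ra$resno[hit[, 2]]),
    dist = d[hit], stringsAsFactors = FALSE
  )
  pair <- paste(df$lig_key, df$rec_key, sep = "\r")
  df <- df[order(pair, df$dist), , drop = FALSE]
  df <- df[!duplicated(paste(df$lig_key, df$rec_key, sep = "\r")), , drop = FALSE]
  names(df)[names(df) == "dist"] <- "min_distance"
  rownames(df) <- NULL
  df
}

#' Run all contact detectors
#' @inheritParams detect_hbonds
#' @return named list of ContactRecord data.frames (hbond, salt_bridge,
#'   pi_cation, hydrophobic) plus close_contacts
#' @export
detect_all_contacts <- function(ligand, receptor, params = contact_params()) {
  list(
    hbond = detect_hbonds(ligand, receptor, params),
    salt_bridge = detect_salt_bridges(ligand, receptor, params),
    pi_cation = detect_pi_cation(ligand, receptor, params),
    hydrophobic = detect_hydrophobic(ligand, receptor, params),
    close_contacts = close_contact_residues(ligand, receptor,
                                            params$close_contact_max)
  )
}

#' Write contact records as TSV
#' @param contacts list from \code{\link{detect_all_contacts}} or a single
#'   ContactRecord data.frame
#' @param path output path
#' @return invisibly, the combined data.frame
#' @export
write_contacts_tsv <- function(contacts, path) {
  if (is.data.frame(contacts)) {
    tab <- contacts
  } else {
    tab <- do.call(rbind, contacts[c("hbond", "salt_bridge", "pi_cation",
                                     "hydrophobic")])
  }
  cols <- c("kind", "lig_res", "rec_res", "class", "lig_atom", "rec_atom",
            "distance", "angle")
  utils::write.table(tab[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tab)
}
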