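# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately written as plain double loops / closed forms, independent of
# the vectorised implementation paths it checks.

# Build a typed Structure from a compact atom table.
# spec: data.frame(name, resname, chain, resno, x, y, z[, het])
toy_structure <- function(spec, typed = TRUE) {
  n <- nrow(spec)
  a <- data.frame(
    record = if (!is.null(spec$het)) ifelse(spec$het, "HETATM", "ATOM") else "ATOM",
    serial = seq_len(n),
    name = spec$name, altloc = " ", resname = spec$resname,
    chain = spec$chain, resno = as.integer(spec$resno), ins = "",
    x = spec$x, y = spec$y, z = spec$z, occ = 1, bfac = 0,
    element = gsub("[0-9]", "", substr(spec$name, 1, 1)),
    stringsAsFactors = FALSE
  )
  a$is_hydrogen <- a$element %in% c("H", "D")
  a$is_het <- a$record == "HETATM"
  a$is_glycan <- a$is_het & a$resname %in% glycan_residue_names()
  s <- structure(list(atoms = a, model_id = 1L,
                      provenance = list(path = "toy", model_index = 1L),
                      typed = FALSE), class = "Structure")
  if (typed) assign_atom_types(s) else s
}

# one-carbon "residue" helper
carbon_at <- function(x, y, z, chain = "A", resno = 1, name = "C1",
                      resname = "LIG") {
  data.frame(name = name, resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# ---- scoring oracle: naive all-pairs double loop ---------------------------
naive_score <- function(receptor, ligand, params = scoring_params()) {
  rm_ <- toxdock:::scoring_atom_mask(receptor)
  lm_ <- toxdock:::scoring_atom_mask(ligand)
  ra <- receptor$atoms[rm_, , drop = FALSE]
  la <- ligand$atoms[lm_, , drop = FALSE]
  w <- params$weights
  total <- 0
  per_rec <- numeric(0)
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      dc <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                   (ra$z[i] - la$z[j])^2)
      if (dc > params$cutoff) next
      d <- dc - ra$xs_radius[i] - la$xs_radius[j]
      g1 <- exp(-(d / 0.5)^2)
      g2 <- exp(-((d - 3) / 2)^2)
      rep_ <- if (d < 0) d^2 else 0
      hyd <- if (ra$is_hydrophobic[i] && la$is_hydrophobic[j]) {
        min(1, max(0, (1.5 - d) / 1))
      } else 0
      hb <- if ((ra$is_donor[i] && la$is_acceptor[j]) ||
                (ra$is_acceptor[i] && la$is_donor[j])) {
        min(1, max(0, (0 - d) / 0.7))
      } else 0
      contrib <- unname(w["gauss1"] * g1 + w["gauss2"] * g2 +
                          w["repulsion"] * rep_ +
                          w["hydrophobic"] * hyd + w["hbond"] * hb)
      total <- total + contrib
      key <- paste0(ra$chain[i], ":", ra$resno[i], ra$ins[i])
      per_rec[key] <- if (is.na(per_rec[key])) contrib else per_rec[key] + contrib
    }
  }
  list(total = total, per_rec = per_rec)
}

# ---- RRCS oracle -----------------------------------------------------------
naive_rrcs_total <- function(ligand, receptor) {
  la <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  ra <- receptor$atoms[!receptor$atoms$is_hydrogen, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(la))) {
    for (j in seq_len(nrow(ra))) {
      d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                  (la$z[i] - ra$z[j])^2)
      total <- total + if (d <= 3.23) 1 else if (d < 4.63) (4.63 - d) / 1.4 else 0
    }
  }
  total
}

# ---- detector oracles (exhaustive pair scans) ------------------------------
naive_hbond_pairs <- function(ligand, receptor, max_d = 3.5) {
  la <- ligand$atoms[toxdock:::scoring_atom_mask(ligand), , drop = FALSE]
  ra <- receptor$atoms[toxdock:::scoring_atom_mask(receptor), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
    d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                (la$z[i] - ra$z[j])^2)
    if (d > max_d + 1e-9) next
    if ((la$is_donor[i] && ra$is_acceptor[j]) ||
        (la$is_acceptor[i] && ra$is_donor[j])) {
      out <- c(out, paste(la$resno[i], ra$resno[j]))
    }
  }
  sort(unique(out))
}

naive_hydrophobic_pairs <- function(ligand, receptor, max_d = 4.5) {
  la <- ligand$atoms[toxdock:::scoring_atom_mask(ligand), , drop = FALSE]
  ra <- receptor$atoms[toxdock:::scoring_atom_mask(receptor), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
    if (!la$is_hydrophobic[i] || !ra$is_hydrophobic[j]) next
    d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                (la$z[i] - ra$z[j])^2)
    if (d <= max_d + 1e-9) out <- c(out, paste(la$resno[i], ra$resno[j]))
  }
  sort(unique(out))
}

naive_salt_bridge_pairs <- function(ligand, receptor, max_d = 4.0) {
  la <- ligand$atoms[toxdock:::scoring_atom_mask(ligand), , drop = FALSE]
  ra <- receptor$atoms[toxdock:::scoring_atom_mask(receptor), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
    pair_ok <-
      (la$formal_charge_class[i] == "cationic" && la$element[i] == "N" &&
         ra$formal_charge_class[j] == "anionic" && ra$element[j] == "O") ||
      (la$formal_charge_class[i] == "anionic" && la$element[i] == "O" &&
         ra$formal_charge_class[j] == "cationic" && ra$element[j] == "N")
    if (!pair_ok) next
    d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                (la$z[i] - ra$z[j])^2)
    if (d <= max_d + 1e-9) out <- c(out, paste(la$resno[i], ra$resno[j]))
  }
  sort(unique(out))
}

# ---- surface closed forms --------------------------------------------------
# accessible area of each of two equal spheres of radius R at center distance d
two_sphere_area_each <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  h <- R - d / 2 # height of the buried cap
  4 * pi * R^2 - 2 * pi * R * h
}

# random rigid transform applied to a Structure (seeded by caller)
random_rigid <- function(s, angle = NULL, axis = NULL, shift = NULL) {
  if (is.null(axis)) axis <- stats::rnorm(3)
  if (is.null(angle)) angle <- stats::runif(1, 0, 2 * pi)
  if (is.null(shift)) shift <- stats::runif(3, -20, 20)
  R <- toxdock:::quat_to_matrix(toxdock:::quat_from_axis_angle(axis, angle))
  set_coords(s, sweep(tcrossprod(coords(s), R), 2, shift, "+"))
}

# contact tables reduced to comparable (kind, pair) sets
contact_pair_set <- function(det) {
  out <- character(0)
  for (k in c("hbond", "salt_bridge", "pi_cation", "hydrophobic")) {
    df <- det[[k]]
    if (nrow(df)) out <- c(out, paste(k, df$rec_key, df$lig_key))
  }
  sort(unique(out))
}

truth_pair_set <- function(truth) {
  tc <- truth$contacts
  sort(unique(paste(tc$kind, paste0("A:", tc$rec_resno),
                    paste0("B:", tc$lig_resno))))
}
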