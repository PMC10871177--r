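# Synthetic bilayer frames with analytically controlled observables.  The
# "lipids" are stick figures -- anchor atoms plus chain carbons with
# explicit hydrogens -- not chemically valid conformers; they are built so
# that (i) the expectation of cos^2(phi) for every C-H bond equals a
# prescribed target, (ii) named groups (terpenoid ring methyls M1-M4, the
# chain double bond) sit at prescribed depth distributions along the
# membrane normal, and (iii) molecule anchors lie on a jittered lattice so
# Voronoi areas have known totals.  That is sufficient, by construction,
# for every trajectory observable in the package to be tested against
# closed-form ground truth.

CH_BOND <- 1.09          # C-H bond length, Angstrom
DB_HALF_SEP <- 0.55      # half the z-separation of the two sp2 carbons

#' Specification of a synthetic bilayer
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (both leaflets are
#'   populated symmetrically).
#' @param composition Fraction of lipids that are terpenoid, in `[0, 1]`.
#' @param target_cos2 Target expectation of `cos^2(phi)` for the C-H bond
#'   vs membrane-normal angle; a single value (all carbons) or one value
#'   per chain carbon position `2..n_carbons`; each in `[0, 1]`.
#' @param group_depths Named list of `c(mean, sd)` depth distributions in
#'   Angstrom (distance from the bilayer midplane) for the terpenoid
#'   methyls `M1`..`M4` and for `double_bond` (the midpoint of the two sp2
#'   carbons).  Groups absent from the list keep their deterministic
#'   built-in placement.
#' @param box_xy In-plane box edge, Angstrom; default sized to ~64
#'   Angstrom^2 per lipid.
#' @param n_frames Number of frames.
#' @param seed Integer seed; the whole build is reproducible under it.
#' @param n_carbons Chain length (carbons, including the carbonyl).
#' @param double_bond Named `c(sn1 = , sn2 = )` Delta positions (`NA` for
#'   saturated).
#' @param tilt_sd_deg Spread of the terpenoid tilt angle, degrees.
#' @return An object of class `synthetic_bilayer_spec`.
#' @export
synthetic_bilayer_spec <- function(n_lipids_per_leaflet,
                                   composition = 1/3,
                                   target_cos2 = 0.5,
                                   group_depths = list(
                                     M1 = c(12, 1), M2 = c(9.5, 1),
                                     M3 = c(7, 1), M4 = c(5, 1),
                                     double_bond = c(9.5, 1)),
                                   box_xy = NULL,
                                   n_frames = 10,
                                   seed = 1,
                                   n_carbons = 18,
                                   double_bond = c(sn1 = NA, sn2 = 9),
                                   tilt_sd_deg = 8) {
  check_number(n_lipids_per_leaflet, "n_lipids_per_leaflet", 1)
  check_number(composition, "composition", 0, 1)
  if (any(target_cos2 < 0) || any(target_cos2 > 1))
    stop_mo("target_cos2 must lie in [0, 1]")
  if (!length(target_cos2) %in% c(1L, n_carbons - 1L))
    stop_mo("target_cos2 must have length 1 or n_carbons - 1 (= %d)",
            n_carbons - 1L)
  if (is.null(box_xy))
    box_xy <- ceiling(sqrt(n_lipids_per_leaflet * 64))
  check_number(box_xy, "box_xy", 0, strict_lower = TRUE)
  check_number(n_frames, "n_frames", 1)
  for (g in names(group_depths)) {
    gd <- group_depths[[g]]
    if (length(gd) != 2L || gd[1] <= 0 || gd[2] < 0)
      stop_mo("group_depths$%s must be c(mean > 0, sd >= 0)", g)
  }
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 composition = composition, target_cos2 = target_cos2,
                 group_depths = group_depths, box_xy = box_xy,
                 n_frames = as.integer(n_frames), seed = seed,
                 n_carbons = as.integer(n_carbons),
                 double_bond = double_bond, tilt_sd_deg = tilt_sd_deg),
            class = "synthetic_bilayer_spec")
}

# cos^2-controlled C-H unit vectors: two-point mixture on cos(phi) -- with
# probability c the bond is parallel to the normal (cos^2 = 1, random
# sign), otherwise it lies in the membrane plane at a uniform azimuth
# (cos^2 = 0), so E[cos^2(phi)] = c exactly.
sample_ch_units <- function(cos2) {
  n <- length(cos2)
  par <- runif(n) < cos2
  psi <- runif(n, 0, 2 * pi)
  u <- cbind(cos(psi), sin(psi), 0)
  u[par, 1:2] <- 0
  u[par, 3] <- sample(c(-1, 1), sum(par), replace = TRUE)
  u
}

# per-chain template rows for one residue; z0 is the unsigned ramp depth
chain_template <- function(ch, chain_label, dx0, z_head = 13, z_tail = 2.5,
                           n_carbons) {
  k <- seq_len(n_carbons)
  ramp <- z_head - (k - 2) * (z_head - z_tail) / (n_carbons - 2)
  ramp[1] <- z_head + 0.8                     # carbonyl sits above carbon 2
  rows <- data.frame(name = ch$carbons, role = "carbon", chain = chain_label,
                     carbon_index = k, dx = dx0 + 0.12 * (-1)^k, dy = 0,
                     z0 = ramp, parent = NA_integer_,
                     stringsAsFactors = FALSE)
  hrows <- do.call(rbind, lapply(k, function(kk) {
    h <- ch$hydrogens[[ch$carbons[kk]]]
    if (!length(h)) return(NULL)
    data.frame(name = h, role = "hydrogen", chain = chain_label,
               carbon_index = kk, dx = dx0, dy = 0, z0 = NA_real_,
               parent = kk, stringsAsFactors = FALSE)
  }))
  list(carbons = rows, hydrogens = hrows)
}

#' Generate synthetic bilayer frames
#'
#' Builds a two-leaflet system of stick-figure lipids on a jittered square
#' lattice per [synthetic_bilayer_spec()], with the bilayer midplane at
#' z = 0, and samples `n_frames` frames in which C-H bond orientations,
#' group depths and terpenoid tilts are redrawn independently.
#'
#' @param spec A [synthetic_bilayer_spec].
#' @return An object of class `bilayer_frames`: list with `atoms` (one row
#'   per atom: `name`, `resname`, `resid`, `leaflet_built`), `coords`
#'   (numeric array `n_atoms x 3 x n_frames`, Angstrom), `box`
#'   (`c(x, y, z)`), `topology` (the matching [chain_topology]) and `spec`.
#' @export
gen_bilayer_frames <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bilayer_spec"))
  with_seed_if(spec$seed, gen_bilayer_frames_impl(spec))
}

gen_bilayer_frames_impl <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  nc <- spec$n_carbons
  topo <- synthetic_topology(nc, spec$double_bond)
  pc_rn <- topo_residues_of_kind(topo, "phospholipid")
  tp_rn <- topo_residues_of_kind(topo, "terpenoid")
  pc <- topo$residues[[pc_rn]]; tp <- topo$residues[[tp_rn]]

  cos2_by_k <- if (length(spec$target_cos2) == 1L)
    rep(spec$target_cos2, nc) else c(NA, spec$target_cos2)

  # residue templates ---------------------------------------------------
  sn1 <- chain_template(pc$chains$sn1, "sn1", -0.8, n_carbons = nc)
  sn2 <- chain_template(pc$chains$sn2, "sn2", +0.8, n_carbons = nc)
  glyc <- data.frame(name = "C2", role = "glycerol", chain = NA,
                     carbon_index = NA, dx = 0.3, dy = 0.6, z0 = 14.5,
                     parent = NA_integer_, stringsAsFactors = FALSE)
  # hydrogens reference carbon rows by chain + carbon_index, resolved below
  pc_tmpl <- rbind(glyc, sn1$carbons, sn2$carbons, sn1$hydrogens,
                   sn2$hydrogens)
  pc_tmpl$dy <- ifelse(pc_tmpl$chain %in% "sn1", -0.5,
                       ifelse(pc_tmpl$chain %in% "sn2", 0.5, pc_tmpl$dy))
  rownames(pc_tmpl) <- NULL
  # resolve hydrogen parents to template row indices
  is_h <- pc_tmpl$role == "hydrogen"
  carb_key <- paste(pc_tmpl$chain, pc_tmpl$carbon_index)
  pc_tmpl$parent_row <- NA_integer_
  pc_tmpl$parent_row[is_h] <- match(carb_key[is_h],
                                    ifelse(pc_tmpl$role == "carbon", carb_key, NA))

  tp_tmpl <- data.frame(
    name = c("O3", "C24", unname(tp$methyls)),
    role = c("terp_anchor", "terp_orient", rep("methyl", 4)),
    chain = NA, carbon_index = NA,
    dx = c(0, 0, 0.7, -0.7, 0.7, -0.7),
    dy = c(0, 0, 0.7, 0.7, -0.7, -0.7),
    z0 = c(12, NA, NA, NA, NA, NA),
    parent = NA_integer_, parent_row = NA_integer_,
    stringsAsFactors = FALSE)

  # lattice sites + composition -----------------------------------------
  nt <- round(spec$composition * n); np <- n - nt
  ngrid <- ceiling(sqrt(n))
  spacing <- spec$box_xy / ngrid
  sx <- (rep(seq_len(ngrid), ngrid)[seq_len(n)] - 0.5) * spacing
  sy <- (rep(seq_len(ngrid), each = ngrid)[seq_len(n)] - 0.5) * spacing

  atoms <- list(); base <- list(); resid0 <- 0L
  for (s in c(1, -1)) {
    jit_x <- runif(n, -0.15, 0.15) * spacing
    jit_y <- runif(n, -0.15, 0.15) * spacing
    kind <- sample(rep(c("pc", "tp"), c(np, nt)))
    for (i in seq_len(n)) {
      tmpl <- if (kind[i] == "pc") pc_tmpl else tp_tmpl
      rn <- if (kind[i] == "pc") pc_rn else tp_rn
      resid0 <- resid0 + 1L
      atoms[[resid0]] <- data.frame(
        name = tmpl$name, resname = rn, resid = resid0,
        leaflet_built = s, role = tmpl$role, chain = tmpl$chain,
        carbon_index = tmpl$carbon_index,
        stringsAsFactors = FALSE)
      base[[resid0]] <- cbind(sx[i] + jit_x[i] + tmpl$dx,
                              sy[i] + jit_y[i] + tmpl$dy,
                              s * tmpl$z0)
    }
  }
  atoms <- do.call(rbind, atoms)
  B <- do.call(rbind, base)
  n_atoms <- nrow(atoms)
  atoms$row <- seq_len(n_atoms)

  # per-frame index sets -------------------------------------------------
  leaflet <- atoms$leaflet_built
  idx_h <- which(atoms$role == "hydrogen")
  # parent carbon row for each hydrogen (same resid, same chain+index)
  key_all <- paste(atoms$resid, atoms$chain, atoms$carbon_index)
  key_carb <- ifelse(atoms$role == "carbon", key_all, NA)
  parent_of_h <- match(key_all[idx_h], key_carb)
  h_cos2 <- cos2_by_k[atoms$carbon_index[idx_h]]

  gd <- spec$group_depths
  idx_db1 <- idx_db2 <- integer()
  if ("double_bond" %in% names(gd)) {
    for (cn in names(pc$chains)) {
      db <- pc$chains[[cn]]$double_bond
      if (is.na(db)) next
      idx_db1 <- c(idx_db1, which(atoms$role == "carbon" &
                                  atoms$chain %in% cn &
                                  atoms$carbon_index == db))
      idx_db2 <- c(idx_db2, which(atoms$role == "carbon" &
                                  atoms$chain %in% cn &
                                  atoms$carbon_index == db + 1L))
    }
  }
  idx_methyl <- lapply(intersect(names(gd), names(tp$methyls)), function(m)
    which(atoms$name == tp$methyls[[m]] & atoms$resname == tp_rn))
  names(idx_methyl) <- intersect(names(gd), names(tp$methyls))
  idx_c24 <- which(atoms$role == "terp_orient")
  idx_o3 <- which(atoms$role == "terp_anchor")
  tilt_sd <- spec$tilt_sd_deg * pi / 180

  coords <- array(NA_real_, c(n_atoms, 3L, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    C <- B
    if (length(idx_db1)) {
      m <- rnorm(length(idx_db1), gd$double_bond[1], gd$double_bond[2])
      C[idx_db1, 3] <- leaflet[idx_db1] * (m + DB_HALF_SEP)
      C[idx_db2, 3] <- leaflet[idx_db2] * (m - DB_HALF_SEP)
    }
    for (mname in names(idx_methyl)) {
      im <- idx_methyl[[mname]]
      if (length(im))
        C[im, 3] <- leaflet[im] * rnorm(length(im), gd[[mname]][1],
                                        gd[[mname]][2])
    }
    if (length(idx_c24)) {
      th <- abs(rnorm(length(idx_c24), 0, tilt_sd))
      ps <- runif(length(idx_c24), 0, 2 * pi)
      L <- 8
      C[idx_c24, 1] <- C[idx_o3, 1] + L * sin(th) * cos(ps)
      C[idx_c24, 2] <- C[idx_o3, 2] + L * sin(th) * sin(ps)
      C[idx_c24, 3] <- C[idx_o3, 3] - leaflet[idx_c24] * L * cos(th)
    }
    if (length(idx_h)) {
      u <- sample_ch_units(h_cos2)
      C[idx_h, ] <- C[parent_of_h, ] + CH_BOND * u
    }
    coords[, , f] <- C
  }

  structure(list(atoms = atoms[c("row", "name", "resname", "resid",
                                 "leaflet_built", "role", "chain",
                                 "carbon_index")],
                 coords = coords,
                 box = c(spec$box_xy, spec$box_xy, 2 * 22),
                 topology = topo, spec = spec, centered = FALSE),
            class = "bilayer_frames")
}

#' @export
print.bilayer_frames <- function(x, ...) {
  cat(sprintf("<bilayer_frames> %d atoms, %d molecules, %d frame(s), box %.1f x %.1f A%s\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              dim(x$coords)[3], x$box[1], x$box[2],
              if (isTRUE(x$centered)) ", centered" else ""))
  invisible(x)
}

n_frames <- function(frames) dim(frames$coords)[3]

#' Write / read bilayer frames as multi-model PDB
#'
#' Frames are written as one `MODEL` per frame through bio3d, a plain-text
#' trajectory carrier any structure viewer reads.  PDB coordinates carry
#' three decimals, so a round trip is exact to 0.001 Angstrom.  The box and
#' the topology are not part of the PDB; supply them to
#' `read_frames_pdb()` (the topology as a YAML file from
#' [write_topology()]).
#'
#' @param frames A `bilayer_frames` object.
#' @param path Output PDB path.
#' @param box For `read_frames_pdb`, the `c(x, y, z)` box in Angstrom.
#' @param topology For `read_frames_pdb`, a [chain_topology] or path to a
#'   topology YAML.
#' @return `read_frames_pdb` returns a `bilayer_frames` object;
#'   `write_frames_pdb` returns `path` invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  stopifnot(inherits(frames, "bilayer_frames"))
  nf <- n_frames(frames)
  xyz <- t(apply(frames$coords, 3L, function(m) as.vector(t(m))))
  xyz <- matrix(xyz, nrow = nf)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = frames$atoms$resid,
                   resid = frames$atoms$resname,
                   elety = frames$atoms$name,
                   chain = ifelse(frames$atoms$leaflet_built %in% -1, "B", "A"))
  invisible(path)
}

#' @rdname write_frames_pdb
#' @export
read_frames_pdb <- function(path, topology, box) {
  if (!file.exists(path)) stop_mo("PDB file not found: %s", path)
  if (is.character(topology)) topology <- read_topology(topology)
  stopifnot(inherits(topology, "chain_topology"), length(box) == 3L)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(pdb$atom)
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  atoms <- data.frame(row = seq_len(na),
                      name = pdb$atom$elety,
                      resname = pdb$atom$resid,
                      resid = pdb$atom$resno,
                      leaflet_built = NA_integer_,
                      stringsAsFactors = FALSE)
  atoms <- annotate_roles(atoms, topology)
  structure(list(atoms = atoms, coords = coords, box = box,
                 topology = topology, spec = NULL, centered = FALSE),
            class = "bilayer_frames")
}

# attach role/chain/carbon_index columns from the topology's atom-name map
annotate_roles <- function(atoms, topology) {
  atoms$role <- NA_character_
  atoms$chain <- NA_character_
  atoms$carbon_index <- NA_integer_
  for (rn in names(topology$residues)) {
    res <- topology$residues[[rn]]
    sel <- atoms$resname == rn
    if (!any(sel)) next
    if (res$kind == "phospholipid") {
      for (cn in names(res$chains)) {
        ch <- res$chains[[cn]]
        ic <- sel & atoms$name %in% ch$carbons
        atoms$role[ic] <- "carbon"
        atoms$chain[ic] <- cn
        atoms$carbon_index[ic] <- match(atoms$name[ic], ch$carbons)
        hyd <- unlist(ch$hydrogens)
        kidx <- rep(seq_along(ch$carbons),
                    vapply(ch$hydrogens, length, integer(1)))
        ih <- sel & atoms$name %in% hyd
        atoms$role[ih] <- "hydrogen"
        atoms$chain[ih] <- cn
        atoms$carbon_index[ih] <- kidx[match(atoms$name[ih], hyd)]
      }
      ig <- sel & atoms$name %in% res$anchors & is.na(atoms$role)
      atoms$role[ig] <- "glycerol"
    } else {
      atoms$role[sel & atoms$name %in% res$anchors] <- "terp_anchor"
      atoms$role[sel & atoms$name %in% res$methyls] <- "methyl"
      if (!is.null(res$orientation))
        atoms$role[sel & atoms$name == res$orientation[["from"]]] <- "terp_orient"
    }
  }
  atoms
}
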