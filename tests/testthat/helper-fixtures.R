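# In-code fixtures shared across test files.  Everything is generated at
# test time; no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# two hand-made pure-component curves sharing a grid, with prescribed
# areas at chosen pressures (piecewise linear between)
hand_curve <- function(pressures, areas, composition = "hand",
                       replicate_id = "r1") {
  isotherm_curve(pressures, areas, composition = composition,
                 replicate_id = replicate_id)
}

# a standard pure pair on a fine grid for mixture tests
pure_pair <- function(noise_sd = 0, seed = NULL,
                      pressures = seq(0.5, 40, by = 0.5)) {
  m1 <- isotherm_model(100, 18, 55, noise_sd = noise_sd,
                       seed = if (is.null(seed)) NULL else seed + 1)
  m2 <- isotherm_model(48, 25, 36, noise_sd = noise_sd,
                       seed = if (is.null(seed)) NULL else seed + 2)
  list(p1 = gen_pure_isotherm(m1, pressures, composition = "PC"),
       p2 = gen_pure_isotherm(m2, pressures, composition = "terp"))
}

# minimal hand-built frames object: one terpenoid per leaflet whose
# C24 -> O3 vector is given explicitly; used for tilt-angle geometry
manual_terp_frames <- function(vecs, o3_z = 10) {
  # vecs: list of length-3 numeric C24->O3 vectors, one molecule each
  topo <- synthetic_topology()
  nm <- length(vecs)
  atoms <- data.frame(row = seq_len(2 * nm),
                      name = rep(c("O3", "C24"), nm),
                      resname = "DPO",
                      resid = rep(seq_len(nm), each = 2),
                      leaflet_built = 1L,
                      role = rep(c("terp_anchor", "terp_orient"), nm),
                      chain = NA, carbon_index = NA,
                      stringsAsFactors = FALSE)
  coords <- array(0, c(2 * nm, 3, 1))
  for (i in seq_len(nm)) {
    o3 <- c(10 * i, 10, o3_z)
    coords[2 * i - 1, , 1] <- o3
    coords[2 * i, , 1] <- o3 - vecs[[i]]
  }
  structure(list(atoms = atoms, coords = coords, box = c(10 * nm + 10, 30, 40),
                 topology = topo, spec = NULL, centered = FALSE),
            class = "bilayer_frames")
}

# hand-built single-selection depth histogram on explicit edges
manual_zhist <- function(edges, density, name = "V1") {
  bw <- diff(edges)[1]
  d <- matrix(density, ncol = 1, dimnames = list(NULL, name))
  structure(list(edges = edges, mids = head(edges, -1) + bw / 2,
                 bin_width = bw, counts = d * 100, density = d, fold = TRUE),
            class = "z_histogram")
}

# wrap a bare point set into a centered single-leaflet frames object so
# voronoi_apl can be exercised on hand-placed anchors
points_frames <- function(pts, L) {
  n <- nrow(pts)
  topo <- synthetic_topology()
  atoms <- data.frame(row = seq_len(n), name = "O3", resname = "DPO",
                      resid = seq_len(n), leaflet_built = 1L,
                      role = "terp_anchor", chain = NA, carbon_index = NA,
                      leaflet = 1L, stringsAsFactors = FALSE)
  coords <- array(0, c(n, 3, 1))
  coords[, 1, 1] <- pts[, 1]; coords[, 2, 1] <- pts[, 2]
  coords[, 3, 1] <- 10
  structure(list(atoms = atoms, coords = coords, box = c(L, L, 40),
                 topology = topo, spec = NULL, centered = TRUE),
            class = "bilayer_frames")
}

# brute-force nearest-anchor pixel-counting oracle for periodic Voronoi
# areas (resolution in Angstrom)
pixel_voronoi_areas <- function(pts, Lx, Ly, resolution = 0.1) {
  gx <- seq(resolution / 2, Lx, by = resolution)
  gy <- seq(resolution / 2, Ly, by = resolution)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  best <- rep(Inf, length(px)); who <- integer(length(px))
  for (i in seq_len(nrow(pts))) {
    dx <- abs(px - pts[i, 1]); dx <- pmin(dx, Lx - dx)
    dy <- abs(py - pts[i, 2]); dy <- pmin(dy, Ly - dy)
    d2 <- dx^2 + dy^2
    sel <- d2 < best
    best[sel] <- d2[sel]; who[sel] <- i
  }
  tabulate(who, nbins = nrow(pts)) * resolution^2
}
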