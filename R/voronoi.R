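# Periodic Voronoi area per lipid.  Each molecule's in-plane position is
# its anchor point (center of geometry of C2/C21/C31 for phospholipids,
# O3 for terpenoids); per leaflet, a 2-D Voronoi tessellation of these
# points is built with the rectangular periodic boundary honoured by
# tiling the 8 neighbouring images and keeping the central-cell polygons.
# This is exact whenever every cell is smaller than the box, and the
# per-leaflet areas then sum to the box cross-section.

wrap_into_box <- function(x, L) x - floor(x / L) * L

# Voronoi cell areas of `pts` (n x 2, already wrapped into [0,Lx) x [0,Ly))
# under periodic boundaries, via deldir on the 3x3 image tiling.
periodic_voronoi_areas <- function(pts, Lx, Ly) {
  n <- nrow(pts)
  sh <- expand.grid(ix = -1:1, iy = -1:1)
  allx <- as.vector(outer(pts[, 1], sh$ix * Lx, "+"))
  ally <- as.vector(outer(pts[, 2], sh$iy * Ly, "+"))
  # central copy occupies the block where ix = iy = 0
  central <- which(sh$ix == 0 & sh$iy == 0)
  idx <- ((central - 1L) * n + 1L):(central * n)
  d <- deldir::deldir(allx, ally,
                      rw = c(-Lx, 2 * Lx, -Ly, 2 * Ly), suppressMsge = TRUE)
  areas <- d$summary$dir.area
  # deldir keeps input order unless duplicates were removed
  if (length(areas) != 9L * n)
    stop_mo("tessellation dropped points; check for coincident anchors")
  areas[idx]
}

#' Voronoi area per lipid
#'
#' Per leaflet, tessellates the molecules' anchor points in the membrane
#' plane (periodic rectangular box honoured by 3x3 image tiling) and
#' returns each molecule's Voronoi cell area.  For every leaflet the areas
#' sum to the box cross-section `box_x * box_y`.
#'
#' @param frames A centered `bilayer_frames` object with leaflets assigned
#'   (see [center_and_assign_leaflets()]).
#' @param frame Frame index (default 1), or a vector of frame indices.
#' @return A data frame of class `voronoi_areas`: `molecule`, `resname`,
#'   `leaflet`, `frame`, `area` (Angstrom^2), with attribute `box_area`.
#' @export
voronoi_apl <- function(frames, frame = 1L) {
  require_centered(frames)
  if (is.null(frames$atoms$leaflet))
    stop_mo("leaflets not assigned; call center_and_assign_leaflets() first")
  Lx <- frames$box[1]; Ly <- frames$box[2]
  at <- frames$atoms
  ids <- unique(at$resid)
  leaf_mol <- at$leaflet[match(ids, at$resid)]
  res_mol <- at$resname[match(ids, at$resid)]
  out <- lapply(frame, function(f) {
    anc <- molecule_anchors(frames, frames$coords[, , f])
    pts <- cbind(wrap_into_box(anc[, "x"], Lx), wrap_into_box(anc[, "y"], Ly))
    res_f <- lapply(unique(leaf_mol), function(s) {
      sel <- which(leaf_mol == s)
      p <- pts[sel, , drop = FALSE]
      dup <- duplicated(round(p / 1e-6))
      if (any(dup))
        stop_mo("coincident anchor points for molecule(s) %s",
                paste(ids[sel][dup], collapse = ", "))
      if (length(sel) < 2L)
        return(data.frame(molecule = ids[sel], resname = res_mol[sel],
                          leaflet = s, frame = f, area = Lx * Ly))
      data.frame(molecule = ids[sel], resname = res_mol[sel], leaflet = s,
                 frame = f, area = periodic_voronoi_areas(p, Lx, Ly))
    })
    do.call(rbind, res_f)
  })
  out <- do.call(rbind, out)
  attr(out, "box_area") <- Lx * Ly
  class(out) <- c("voronoi_areas", "data.frame")
  out
}

#' Per-leaflet Voronoi area totals
#'
#' @param areas A [voronoi_apl()] result.
#' @return Data frame with one row per (frame, leaflet): total area and
#'   its relative deviation from the box cross-section.
#' @export
voronoi_totals <- function(areas) {
  stopifnot(inherits(areas, "voronoi_areas"))
  box <- attr(areas, "box_area")
  agg <- aggregate(area ~ frame + leaflet, data = areas, FUN = sum)
  agg$rel_error <- (agg$area - box) / box
  agg
}
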