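# Bilayer trajectory observables.  The membrane normal is the z axis
# throughout (frames must be built or pre-aligned that way); no
# instantaneous-normal or curvature correction is applied, matching
# flat-bilayer simulation conventions.

# per-molecule in-plane anchor position and anchor z, for one frame matrix
molecule_anchors <- function(frames, C) {
  at <- frames$atoms
  topo <- frames$topology
  anchor <- logical(nrow(at))
  for (rn in names(topo$residues)) {
    res <- topo$residues[[rn]]
    anchor <- anchor | (at$resname == rn & at$name %in% res$anchors)
  }
  if (!any(anchor)) stop_mo("no anchor atoms found for any residue")
  ids <- unique(at$resid)
  miss <- setdiff(ids, unique(at$resid[anchor]))
  if (length(miss))
    stop_mo("molecule(s) %s (residue %s) have no anchor atoms present",
            paste(head(miss, 5), collapse = ","),
            paste(unique(at$resname[at$resid %in% miss]), collapse = ","))
  sub <- at[anchor, ]
  g <- factor(sub$resid, levels = ids)
  cbind(x = tapply(C[anchor, 1], g, mean),
        y = tapply(C[anchor, 2], g, mean),
        z = tapply(C[anchor, 3], g, mean))
}

#' Center frames on the bilayer midplane and assign leaflets
#'
#' For every frame, the midplane is the mean z of all molecules' anchor
#' points (the C2/C21/C31 center of geometry for phospholipids, O3 for
#' terpenoids); all z coordinates are shifted so the midplane sits at
#' z = 0.  Each molecule is then labelled by the sign of its anchor z
#' (`+1` upper leaflet, `-1` lower).  A single-leaflet input is accepted
#' with a warning.
#'
#' @param frames A `bilayer_frames` object.
#' @return The same object with `centered = TRUE` and a `leaflet` column
#'   in `$atoms` (per-molecule label from the first frame).
#' @export
center_and_assign_leaflets <- function(frames) {
  stopifnot(inherits(frames, "bilayer_frames"))
  nf <- n_frames(frames)
  leaf <- NULL
  for (f in seq_len(nf)) {
    anc <- molecule_anchors(frames, frames$coords[, , f])
    frames$coords[, 3, f] <- frames$coords[, 3, f] - mean(anc[, "z"])
    if (f == 1L) {
      zc <- anc[, "z"] - mean(anc[, "z"])
      leaf <- ifelse(zc >= 0, 1L, -1L)
    }
  }
  if (length(unique(leaf)) < 2L)
    warning("all molecules fall in a single leaflet", call. = FALSE)
  ids <- unique(frames$atoms$resid)
  frames$atoms$leaflet <- leaf[match(frames$atoms$resid, ids)]
  frames$centered <- TRUE
  frames
}

require_centered <- function(frames) {
  if (!isTRUE(frames$centered))
    stop_mo("frames are not centered; call center_and_assign_leaflets() first")
  frames
}

#' Deuterium order parameter profile
#'
#' Computes, for every chain carbon,
#' \deqn{S_{CD} = \tfrac{1}{2} \langle 3\cos^2\phi - 1 \rangle}
#' where phi is the angle between each C-H bond vector and the membrane
#' normal (z), averaged over that carbon's hydrogens, molecules and
#' frames.  Values lie in `[-0.5, 1]`: +1 for bonds parallel to the
#' normal, -0.5 for bonds in the membrane plane, 0 for isotropic bonds.
#' Carbonyl carbons (no hydrogen) are skipped; sp2 carbons contribute
#' through their single vinyl hydrogen.  The standard error is obtained by
#' block averaging over contiguous frame blocks.
#'
#' @param frames A `bilayer_frames` object.
#' @param chain Chain label (e.g. `"sn1"`, `"sn2"`).
#' @param resname Phospholipid residue name; defaults to the topology's
#'   (only) phospholipid.
#' @param blocks Number of frame blocks for the standard error (default 5;
#'   reduced if there are fewer frames).
#' @return A data frame of class `order_profile`: `carbon_index`, `carbon`,
#'   `scd`, `abs_scd`, `se`, `n_samples`, `chain`.
#' @export
scd_profile <- function(frames, chain = "sn2", resname = NULL, blocks = 5) {
  stopifnot(inherits(frames, "bilayer_frames"))
  topo <- frames$topology
  resname <- resname %||% topo_residues_of_kind(topo, "phospholipid")[1]
  res <- topo$residues[[resname]]
  if (is.null(res)) stop_mo("residue %s not in topology", resname)
  ch <- res$chains[[chain]]
  if (is.null(ch)) stop_mo("chain %s not in residue %s", chain, resname)
  at <- frames$atoms
  nf <- n_frames(frames)
  blocks <- max(1L, min(as.integer(blocks), nf))
  block_of <- cut(seq_len(nf), blocks, labels = FALSE)

  keep_k <- which(vapply(ch$carbons, function(k)
    length(ch$hydrogens[[k]]) > 0L, logical(1)))
  bad <- setdiff(seq_along(ch$carbons),
                 union(keep_k, match(ch$carbonyl, ch$carbons)))
  if (length(bad))
    stop_mo("carbon(s) %s have no hydrogens and no carbonyl/sp2 annotation",
            paste(ch$carbons[bad], collapse = ", "))

  out <- lapply(keep_k, function(k) {
    cname <- ch$carbons[k]
    hnames <- ch$hydrogens[[cname]]
    ic <- which(at$resname == resname & at$name == cname)
    ih <- which(at$resname == resname & at$name %in% hnames)
    if (!length(ih))
      stop_mo("no hydrogens found in frames for carbon %s", cname)
    # match each hydrogen row to its carbon row by resid
    ic_of_h <- ic[match(at$resid[ih], at$resid[ic])]
    block_means <- numeric(blocks); ntot <- 0L; ssum <- 0
    for (b in seq_len(blocks)) {
      fr <- which(block_of == b)
      v <- frames$coords[ih, , fr, drop = FALSE] -
           frames$coords[ic_of_h, , fr, drop = FALSE]
      cz2 <- (v[, 3, ]^2) / (v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
      s <- 0.5 * (3 * cz2 - 1)
      block_means[b] <- mean(s)
      ntot <- ntot + length(s); ssum <- ssum + sum(s)
    }
    se <- if (blocks > 1L) sd(block_means) / sqrt(blocks) else NA_real_
    data.frame(carbon_index = k, carbon = cname, scd = ssum / ntot,
               abs_scd = abs(ssum / ntot), se = se, n_samples = ntot,
               chain = chain, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("order_profile", "data.frame")
  out
}

# resolve a named group to per-molecule z samples for one frame
group_z_values <- function(frames, group, C) {
  at <- frames$atoms
  topo <- frames$topology
  tp_rn <- topo_residues_of_kind(topo, "terpenoid")
  # terpenoid methyl role names (M1..M4)
  for (rn in tp_rn) {
    m <- topo$residues[[rn]]$methyls
    if (group %in% names(m))
      return(C[at$resname == rn & at$name == m[[group]], 3])
  }
  # double bond: midpoint of the two sp2 carbon z's, optionally ":chain"
  if (startsWith(group, "double_bond")) {
    want_chain <- sub("^double_bond:?", "", group)
    zz <- numeric()
    for (rn in topo_residues_of_kind(topo, "phospholipid")) {
      res <- topo$residues[[rn]]
      for (cn in names(res$chains)) {
        if (nzchar(want_chain) && cn != want_chain) next
        ch <- res$chains[[cn]]
        if (is.na(ch$double_bond)) next
        c1 <- ch$carbons[ch$double_bond]
        c2 <- ch$carbons[ch$double_bond + 1L]
        z1 <- C[at$resname == rn & at$name == c1, 3]
        z2 <- C[at$resname == rn & at$name == c2, 3]
        zz <- c(zz, (z1 + z2) / 2)
      }
    }
    return(zz)
  }
  # plain atom name, any residue
  C[at$name == group, 3]
}

#' Membrane-normal depth distributions of named groups
#'
#' Histograms the z positions of named selections along the membrane
#' normal on a common uniform grid (bin width 0.87 Angstrom by default),
#' with the bilayer midplane at z = 0.  Selections are terpenoid methyl
#' roles (`"M1"`..`"M4"`), `"double_bond"` (midpoint of the two sp2 chain
#' carbons; suffix `":sn1"`/`":sn2"` selects a chain), or any literal atom
#' name.  With `fold = TRUE` (default) the lower leaflet is reflected
#' through z = 0 and distances |z| are binned.
#'
#' @param frames A centered `bilayer_frames` object (see
#'   [center_and_assign_leaflets()]).
#' @param groups Character vector of selection names.
#' @param bin_width Bin width, Angstrom.
#' @param fold Reflect the lower leaflet through the midplane.
#' @param edges Optional explicit bin edges (uniform, increasing).
#' @return An object of class `z_histogram`: `edges`, `mids`, `counts`
#'   and `density` (matrices, one column per group; each density column
#'   integrates to 1).
#' @export
group_z_distribution <- function(frames, groups = c("M1", "M2", "M3", "M4",
                                                    "double_bond"),
                                 bin_width = 0.87, fold = TRUE,
                                 edges = NULL) {
  require_centered(frames)
  check_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  nf <- n_frames(frames)
  zs <- lapply(groups, function(g) {
    z <- unlist(lapply(seq_len(nf), function(f)
      group_z_values(frames, g, frames$coords[, , f])))
    if (!length(z)) stop_mo("selection '%s' matches no atoms", g)
    if (fold) abs(z) else z
  })
  names(zs) <- groups
  if (is.null(edges)) {
    lo <- if (fold) 0 else floor(min(unlist(zs)) / bin_width) * bin_width
    hi <- max(unlist(zs))
    edges <- seq(lo, hi + bin_width, by = bin_width)
  } else {
    if (length(edges) < 2L || any(diff(edges) <= 0) ||
        diff(range(diff(edges))) > 1e-9)
      stop_mo("`edges` must be uniform and increasing")
    bin_width <- diff(edges)[1]
    rng <- range(unlist(zs))
    if (rng[1] < edges[1] || rng[2] > edges[length(edges)])
      stop_mo("samples fall outside the supplied bin edges")
  }
  counts <- vapply(zs, function(z)
    tabulate(findInterval(z, edges, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(edges) - 1L),
    numeric(length(edges) - 1L))
  counts <- matrix(counts, ncol = length(groups),
                   dimnames = list(NULL, groups))
  dens <- sweep(counts, 2L, colSums(counts) * bin_width, "/")
  structure(list(edges = edges, mids = head(edges, -1) + bin_width / 2,
                 bin_width = bin_width, counts = counts, density = dens,
                 fold = fold),
            class = "z_histogram")
}

#' @export
print.z_histogram <- function(x, ...) {
  cat(sprintf("<z_histogram> %d bins of %.3g A, groups: %s%s\n",
              length(x$mids), x$bin_width,
              paste(colnames(x$density), collapse = ", "),
              if (x$fold) " (leaflet-folded)" else ""))
  invisible(x)
}

#' Overlap coefficient of two depth distributions
#'
#' \deqn{OVL = \sum_{bins} \min(d_1, d_2) \cdot w}
#' for normalized densities d1, d2 on identical bin edges; 1 for
#' identical distributions, 0 for disjoint supports, symmetric in its
#' arguments.
#'
#' @param h1 A [group_z_distribution()] result.
#' @param sel1,sel2 Group (column) names.
#' @param h2 Optional second `z_histogram` holding `sel2`; must share
#'   `h1`'s bin edges exactly.  Defaults to `h1`.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(h1, sel1, sel2, h2 = h1) {
  stopifnot(inherits(h1, "z_histogram"), inherits(h2, "z_histogram"))
  if (length(h1$edges) != length(h2$edges) ||
      any(abs(h1$edges - h2$edges) > 1e-9))
    stop_mo("histograms have mismatched bin edges")
  for (s in list(c(sel1, "sel1"), c(sel2, "sel2"))) {
    hh <- if (s[2] == "sel1") h1 else h2
    if (!s[1] %in% colnames(hh$density))
      stop_mo("selection '%s' not present in the histogram", s[1])
  }
  sum(pmin(h1$density[, sel1], h2$density[, sel2])) * h1$bin_width
}

#' Terpenoid tilt-angle distribution
#'
#' The angle between each terpenoid's orientation vector (from the `C24`
#' ring atom to the `O3` hydroxyl oxygen, per the topology's `orientation`
#' entry) and the membrane normal, folded to `[0, 90]` degrees so the
#' measure is agnostic to which leaflet the molecule sits in.
#'
#' @param frames A `bilayer_frames` object.
#' @param resname Terpenoid residue name; defaults to the topology's
#'   (only) terpenoid.
#' @return A list of class `tilt_distribution`: `angles` (degrees, one per
#'   molecule per frame), `mean`, `median`, `n`.
#' @export
tilt_distribution <- function(frames, resname = NULL) {
  stopifnot(inherits(frames, "bilayer_frames"))
  topo <- frames$topology
  resname <- resname %||% topo_residues_of_kind(topo, "terpenoid")[1]
  res <- topo$residues[[resname]]
  if (is.null(res) || is.null(res$orientation))
    stop_mo("residue %s has no orientation vector in the topology", resname)
  at <- frames$atoms
  ifrom <- which(at$resname == resname & at$name == res$orientation[["from"]])
  ito <- which(at$resname == resname & at$name == res$orientation[["to"]])
  if (!length(ifrom) || !length(ito))
    stop_mo("orientation atom %s missing for residue %s",
            if (!length(ifrom)) res$orientation[["from"]]
            else res$orientation[["to"]], resname)
  ifrom <- ifrom[match(at$resid[ito], at$resid[ifrom])]
  if (anyNA(ifrom))
    stop_mo("orientation atom %s missing for some %s molecules",
            res$orientation[["from"]], resname)
  nf <- n_frames(frames)
  ang <- unlist(lapply(seq_len(nf), function(f) {
    v <- frames$coords[ito, , f, drop = FALSE] -
         frames$coords[ifrom, , f, drop = FALSE]
    cz <- abs(v[, 3, 1]) / sqrt(rowSums(v[, , 1, drop = FALSE]^2))
    acos(pmin(1, pmax(0, cz))) * 180 / pi
  }))
  structure(list(angles = ang, mean = mean(ang), median = median(ang),
                 n = length(ang)),
            class = "tilt_distribution")
}

#' @export
print.tilt_distribution <- function(x, ...) {
  cat(sprintf("<tilt_distribution> n = %d, mean %.2f deg, median %.2f deg\n",
              x$n, x$mean, x$median))
  invisible(x)
}
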