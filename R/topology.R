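# Chain topology: the per-residue map from atom names to structural roles
# (chain carbons and their hydrogens, double-bond position, terpenoid methyls
# and anchor atoms) that every trajectory observable consults instead of
# hard-coding a naming convention.

#' Per-residue chain topology
#'
#' A `chain_topology` maps residue names to the atom-name roles used by the
#' trajectory observables: ordered chain carbons with their attached
#' hydrogens, the double-bond position, terpenoid ring methyl groups
#' (M1--M4), the anchor atoms that define a molecule's in-plane position
#' (glycerol `C2` and the carbonyl carbons `C21`/`C31` for phospholipids,
#' the hydroxyl oxygen `O3` for terpenoids), and the `C24 -> O3` orientation
#' vector of the terpenoid.
#'
#' Double-bond positions follow the Delta-n convention: `Delta n` is the
#' bond between chain carbons `n` and `n + 1`, counted from the carbonyl
#' carbon (carbon 1).  Chain carbons must each carry at least one hydrogen
#' unless annotated as a carbonyl (no hydrogen, skipped in order-parameter
#' profiles) or as sp2 (a single vinyl hydrogen).
#'
#' @param residues Named list, one entry per residue name.  Each entry is a
#'   list with fields `kind` (`"phospholipid"` or `"terpenoid"`); for
#'   phospholipids `anchors` (character), `chains` (named list of chains,
#'   each with `carbons`, `hydrogens` (named list, one character vector per
#'   carbon), `carbonyl` (character), `sp2` (character), `double_bond`
#'   (integer Delta position or `NA`)); for terpenoids `anchors`, `methyls`
#'   (named `M1`..`M4` character vector of atom names) and `orientation`
#'   (`c(from = , to = )`).
#' @return An object of class `chain_topology`.
#' @seealso [synthetic_topology()] for the generator-matched default,
#'   [read_topology()]/[write_topology()] for the YAML on-disk form.
#' @export
chain_topology <- function(residues) {
  if (!is.list(residues) || is.null(names(residues)) || any(names(residues) == ""))
    stop_mo("`residues` must be a named list keyed by residue name")
  for (rn in names(residues)) {
    res <- residues[[rn]]
    kind <- res$kind %||% stop_mo("residue %s: missing `kind`", rn)
    if (!kind %in% c("phospholipid", "terpenoid"))
      stop_mo("residue %s: unknown kind '%s'", rn, kind)
    if (kind == "phospholipid") {
      if (is.null(res$chains) || !length(res$chains))
        stop_mo("residue %s: phospholipid needs at least one chain", rn)
      for (cn in names(res$chains)) {
        ch <- res$chains[[cn]]
        if (is.null(ch$carbons) || !length(ch$carbons))
          stop_mo("residue %s chain %s: empty carbon list", rn, cn)
        hyd <- ch$hydrogens
        if (!setequal(names(hyd), ch$carbons))
          stop_mo("residue %s chain %s: hydrogens must be keyed by carbon name",
                  rn, cn)
        special <- c(ch$carbonyl %||% character(), ch$sp2 %||% character())
        bare <- ch$carbons[vapply(ch$carbons, function(k) length(hyd[[k]]) == 0L,
                                  logical(1))]
        bad <- setdiff(bare, special)
        if (length(bad))
          stop_mo("residue %s chain %s: carbon(s) %s have no hydrogens and no carbonyl/sp2 annotation",
                  rn, cn, paste(bad, collapse = ", "))
        db <- ch$double_bond %||% NA_integer_
        if (!is.na(db)) {
          if (db < 1L || db + 1L > length(ch$carbons))
            stop_mo("residue %s chain %s: double bond Delta-%d outside the chain",
                    rn, cn, db)
        }
      }
    } else {
      if (is.null(res$anchors) || !all(nzchar(res$anchors)))
        stop_mo("residue %s: terpenoid needs anchor atom names", rn)
      if (!is.null(res$orientation) &&
          !all(c("from", "to") %in% names(res$orientation)))
        stop_mo("residue %s: orientation needs `from` and `to`", rn)
    }
  }
  structure(list(residues = residues), class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("<chain_topology>", length(x$residues), "residue(s)\n")
  for (rn in names(x$residues)) {
    res <- x$residues[[rn]]
    if (res$kind == "phospholipid") {
      dbs <- vapply(res$chains, function(ch)
        if (is.na(ch$double_bond %||% NA)) "sat" else paste0("D", ch$double_bond),
        character(1))
      cat(sprintf("  %s (phospholipid): chains %s\n", rn,
                  paste(sprintf("%s[%s]", names(res$chains), dbs), collapse = ", ")))
    } else {
      cat(sprintf("  %s (terpenoid): methyls %s, anchors %s\n", rn,
                  paste(res$methyls, collapse = ","),
                  paste(res$anchors, collapse = ",")))
    }
  }
  invisible(x)
}

# CHARMM-like atom naming for one synthetic acyl chain: carbons C<p>1..C<p>n
# with C<p>1 the carbonyl; hydrogens H<k><s1>/H<k><s2>; sp2 carbons keep a
# single vinyl hydrogen.
build_chain <- function(prefix, n_carbons, double_bond = NA,
                        h_suffix = c("X", "Y")) {
  carbons <- paste0("C", prefix, seq_len(n_carbons))
  sp2 <- if (!is.na(double_bond)) carbons[c(double_bond, double_bond + 1L)]
         else character()
  hyd <- lapply(seq_len(n_carbons), function(k) {
    if (k == 1L) return(character())            # carbonyl carbon
    h <- paste0("H", k, h_suffix)
    if (carbons[k] %in% sp2) h[1] else h
  })
  names(hyd) <- carbons
  list(carbons = carbons, hydrogens = hyd, carbonyl = carbons[1],
       sp2 = sp2, double_bond = if (is.na(double_bond)) NA_integer_
                                else as.integer(double_bond))
}

#' Topology of the synthetic stick-figure bilayer
#'
#' Returns the `chain_topology` matching [gen_bilayer_frames()]: a
#' two-chain phosphatidylcholine-like residue (`pc_resname`, default `SPC`)
#' with glycerol anchor `C2`, carbonyl anchors `C21`/`C31`, chain carbons
#' `C2k`/`C3k` and explicit hydrogens, and a terpenoid residue
#' (`terp_resname`, default `DPO`) with hydroxyl anchor `O3`, orientation
#' atom `C24` and ring methyl carbons `M1`--`M4`.
#'
#' @param n_carbons Chain length in carbons including the carbonyl.
#' @param double_bond Named vector `c(sn1 = , sn2 = )` of Delta positions
#'   (`NA` for a saturated chain).
#' @param pc_resname,terp_resname Residue names used in generated frames.
#' @return A [chain_topology] object.
#' @export
synthetic_topology <- function(n_carbons = 18,
                               double_bond = c(sn1 = NA, sn2 = 9),
                               pc_resname = "SPC", terp_resname = "DPO") {
  db <- c(sn1 = unname(double_bond["sn1"]), sn2 = unname(double_bond["sn2"]))
  chain_topology(setNames(list(
    list(kind = "phospholipid",
         anchors = c("C2", "C21", "C31"),
         chains = list(
           sn1 = build_chain(3, n_carbons, db["sn1"], c("X", "Y")),
           sn2 = build_chain(2, n_carbons, db["sn2"], c("R", "S")))),
    list(kind = "terpenoid",
         anchors = "O3",
         methyls = c(M1 = "M1", M2 = "M2", M3 = "M3", M4 = "M4"),
         orientation = c(from = "C24", to = "O3"))),
    c(pc_resname, terp_resname)))
}

# role lookup helpers --------------------------------------------------------

topo_residues_of_kind <- function(topology, kind) {
  names(topology$residues)[vapply(topology$residues,
                                  function(r) r$kind == kind, logical(1))]
}

topo_anchor_atoms <- function(topology, resname) {
  topology$residues[[resname]]$anchors
}

#' Write / read a chain topology as YAML
#'
#' The on-disk form is a structured text config keyed by residue name, so a
#' topology can accompany trajectory files produced elsewhere.
#'
#' @param topology A [chain_topology].
#' @param path File path.
#' @return `read_topology` returns a [chain_topology]; `write_topology`
#'   returns `path` invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "chain_topology"))
  res <- topology$residues
  # yaml maps need lists: named atomic vectors would lose their names
  for (rn in names(res)) {
    if (res[[rn]]$kind == "terpenoid") {
      res[[rn]]$methyls <- as.list(res[[rn]]$methyls)
      if (!is.null(res[[rn]]$orientation))
        res[[rn]]$orientation <- as.list(res[[rn]]$orientation)
    }
  }
  yaml::write_yaml(res, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_mo("topology file not found: %s", path)
  res <- yaml::read_yaml(path)
  # YAML loses the named-vector structure of `orientation` and `methyls`
  for (rn in names(res)) {
    r <- res[[rn]]
    if (identical(r$kind, "terpenoid")) {
      res[[rn]]$methyls <- unlist(r$methyls)
      res[[rn]]$orientation <- unlist(r$orientation)
      res[[rn]]$anchors <- unlist(r$anchors)
    } else if (identical(r$kind, "phospholipid")) {
      res[[rn]]$anchors <- unlist(r$anchors)
      for (cn in names(r$chains)) {
        ch <- r$chains[[cn]]
        res[[rn]]$chains[[cn]]$carbons <- unlist(ch$carbons)
        res[[rn]]$chains[[cn]]$hydrogens <-
          lapply(ch$hydrogens, function(h) as.character(unlist(h)))
        res[[rn]]$chains[[cn]]$double_bond <-
          if (is.null(ch$double_bond)) NA_integer_ else as.integer(ch$double_bond)
      }
    }
  }
  chain_topology(res)
}
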