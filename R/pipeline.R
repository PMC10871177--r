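# Orchestration: one seed-reproducible run over the generator and the
# three analysis stages, writing tab-separated result tables plus a
# manifest with checksums, and an end-to-end selftest asserting the
# module invariants.

#' Build a pipeline run configuration
#'
#' All seeds are explicit (no wall-clock defaults); every output of
#' [run_pipeline()] carries a hash of the configuration for provenance.
#'
#' @param stages Subset of `c("simulate", "isotherm", "traj", "assay")`.
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @param inputs Named list of input file paths (`mix`, `pure1`, `pure2`
#'   isotherm CSVs; `growth`, `lysis` assay CSVs; `frames_pdb`,
#'   `topology`, `box` for trajectories).  Stages with no inputs fall
#'   back to the built-in generators (a "generator-only" run).
#' @param x1 Mole fraction of the phospholipid in the mixture.
#' @param pressure Condensation reference pressure, mN/m.
#' @param bin_width Depth-histogram bin width, Angstrom.
#' @param od_window Growth-rate OD window.
#' @param report_at Lysis reporting buffer percentage.
#' @param generator Options for the generator stanza (list; see
#'   [synthetic_bilayer_spec()] for the bilayer fields).
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "isotherm", "traj", "assay"),
                       seed = 1, out_dir = "memorder_out",
                       inputs = list(), x1 = 2/3, pressure = 30,
                       bin_width = 0.87, od_window = c(0.75, 0.40),
                       report_at = 80, generator = list()) {
  known <- c("simulate", "isotherm", "traj", "assay")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop_mo("unknown stage(s): %s (known: %s)", paste(bad, collapse = ", "),
            paste(known, collapse = ", "))
  if (is.null(seed)) stop_mo("`seed` must be given explicitly")
  structure(list(stages = stages, seed = as.integer(seed), out_dir = out_dir,
                 inputs = inputs, x1 = x1, pressure = pressure,
                 bin_width = bin_width, od_window = od_window,
                 report_at = report_at, generator = generator),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_mo("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# default synthetic study conditions used when a stage has no input files:
# a PC-like lipid vs a more condensed terpenoid, a 2:1 mixture with a
# -4 A^2 excess area, a D9-like vs D11-like bilayer pair, and assay
# fixtures with known rates and fractions.
default_generator <- function(seed, gen = list()) {
  list(
    pressures = gen$pressures %||% seq(0.5, 40, by = 0.5),
    pc = isotherm_model(100, 18, 55, noise_sd = gen$noise_sd %||% 0.8,
                        seed = seed + 11),
    terp = isotherm_model(48, 25, 36, noise_sd = gen$noise_sd %||% 0.8,
                          seed = seed + 12),
    excess = gen$excess %||% -4,
    x1 = gen$x1 %||% 2/3,
    n_replicates = gen$n_replicates %||% 3L,
    bilayer = list(
      n_lipids_per_leaflet = gen$n_lipids_per_leaflet %||% 50L,
      n_frames = gen$n_frames %||% 20L,
      target_cos2 = gen$target_cos2 %||% 0.5),
    growth_rates = gen$growth_rates %||% c(d9 = 0.045, d11 = 0.060),
    lysis_fractions = gen$lysis_fractions %||% c(d9 = 0.65, d11 = 0.35),
    assay_noise = gen$assay_noise %||% 0.01)
}

simulate_stage <- function(config, dir) {
  g <- default_generator(config$seed, config$generator)
  paths <- list()
  # isotherm replicates: three per composition
  reps <- function(model, label, seed0) lapply(seq_len(g$n_replicates),
    function(r) {
      m <- model; m$seed <- seed0 + r
      gen_pure_isotherm(m, g$pressures, composition = label,
                        replicate_id = paste0("r", r))
    })
  pure1 <- reps(g$pc, "PC", config$seed + 100)
  pure2 <- reps(g$terp, "terpenoid", config$seed + 200)
  truth <- mixture_ground_truth(c(g$x1, 1 - g$x1), g$excess)
  p1_clean <- gen_pure_isotherm(
    within_noiseless(g$pc), g$pressures, composition = "PC")
  p2_clean <- gen_pure_isotherm(
    within_noiseless(g$terp), g$pressures, composition = "terpenoid")
  mix <- lapply(seq_len(g$n_replicates), function(r)
    gen_mixture_isotherm(p1_clean, p2_clean, truth,
                         noise_sd = g$pc$noise_sd, seed = config$seed + 300 + r,
                         composition = "PC:terpenoid",
                         replicate_id = paste0("r", r)))
  paths$pure1 <- write_isotherms(pure1, file.path(dir, "pure1.csv"))
  paths$pure2 <- write_isotherms(pure2, file.path(dir, "pure2.csv"))
  paths$mix <- write_isotherms(mix, file.path(dir, "mix.csv"))

  # a D9-like and a D11-like bilayer (double-bond depth at M2 vs between
  # M3 and M4)
  mk_spec <- function(db, db_depth, seed) {
    synthetic_bilayer_spec(
      n_lipids_per_leaflet = g$bilayer$n_lipids_per_leaflet,
      composition = 1/3, target_cos2 = g$bilayer$target_cos2,
      group_depths = list(M1 = c(12, 1), M2 = c(9.5, 1), M3 = c(7, 1),
                          M4 = c(5, 1), double_bond = c(db_depth, 1)),
      n_frames = g$bilayer$n_frames, seed = seed,
      double_bond = c(sn1 = NA, sn2 = db))
  }
  fr9 <- gen_bilayer_frames(mk_spec(9, 9.5, config$seed + 400))
  fr11 <- gen_bilayer_frames(mk_spec(11, 6.0, config$seed + 500))
  paths$frames_d9 <- write_frames_pdb(fr9, file.path(dir, "bilayer_d9.pdb"))
  paths$frames_d11 <- write_frames_pdb(fr11, file.path(dir, "bilayer_d11.pdb"))
  paths$topology <- write_topology(fr9$topology,
                                   file.path(dir, "topology.yaml"))

  # assays: 3 replicates per diet
  gcs <- do.call(rbind, lapply(names(g$growth_rates), function(d)
    do.call(rbind, lapply(1:3, function(r) {
      gc <- gen_growth_curve(g$growth_rates[[d]], od_start = 0.9,
                             noise_sd = g$assay_noise,
                             seed = config$seed + 600 +
                               10 * match(d, names(g$growth_rates)) + r,
                             diet = d)
      data.frame(sample = paste0(d, "_r", r), time_h = gc$time_h,
                 od562 = gc$od562, diet = d)
    }))))
  paths$growth <- file.path(dir, "growth.csv")
  write.csv(gcs, paths$growth, row.names = FALSE, quote = FALSE)
  lp <- gen_lysis_plate(rep(unname(g$lysis_fractions), each = 3),
                        noise_sd = 5, seed = config$seed + 700,
                        diet = rep(names(g$lysis_fractions), each = 3))
  paths$lysis <- file.path(dir, "lysis.csv")
  write.csv(lp$data, paths$lysis, row.names = FALSE, quote = FALSE)
  list(paths = paths, frames = list(d9 = fr9, d11 = fr11))
}

within_noiseless <- function(model) { model$noise_sd <- 0; model }

isotherm_stage <- function(config, inputs, dir) {
  for (nm in c("mix", "pure1", "pure2"))
    if (is.null(inputs[[nm]]))
      stop_mo("isotherm stage: missing input `%s`", nm)
  mix <- average_replicates(read_isotherms(inputs$mix))
  p1 <- average_replicates(read_isotherms(inputs$pure1))
  p2 <- average_replicates(read_isotherms(inputs$pure2))
  cond <- condensation(mix, p1, p2, X1 = config$x1,
                       pressure = config$pressure)
  dg <- excess_mixing_energy(mix, p1, p2, X1 = config$x1)
  man <- compare_isotherm_groups(list(
    mix = read_isotherms(inputs$mix), pure1 = read_isotherms(inputs$pure1)))
  write_tsv(data.frame(
    quantity = c("condensation_pct", "condensation_sd_pct",
                 "dgmix_J_per_mol", "dgmix_sd_J_per_mol",
                 "manova_F", "manova_p"),
    value = c(cond$c, cond$sd, dg$delta_g, dg$sd, man$F, man$p)),
    file.path(dir, "isotherm_results.tsv"))
}

traj_stage <- function(config, inputs, dir, frames = NULL) {
  fr <- frames
  if (is.null(fr)) {
    for (nm in c("frames_pdb", "topology"))
      if (is.null(inputs[[nm]]))
        stop_mo("traj stage: missing input `%s`", nm)
    fr <- list(run = read_frames_pdb(inputs$frames_pdb, inputs$topology,
                                     inputs$box %||% c(60, 60, 44)))
  }
  for (label in names(fr)) {
    f <- center_and_assign_leaflets(fr[[label]])
    prof <- scd_profile(f, chain = "sn2")
    write_tsv(as.data.frame(prof),
              file.path(dir, sprintf("scd_%s.tsv", label)))
    zh <- group_z_distribution(f, bin_width = config$bin_width)
    write_tsv(data.frame(z_mid = zh$mids, zh$density, check.names = FALSE),
              file.path(dir, sprintf("zhist_%s.tsv", label)))
    ov <- expand.grid(group = c("M1", "M2", "M3", "M4"),
                      stringsAsFactors = FALSE)
    ov$overlap_with_double_bond <- vapply(ov$group, function(m)
      overlap_coefficient(zh, "double_bond", m), numeric(1))
    write_tsv(ov, file.path(dir, sprintf("overlap_%s.tsv", label)))
    va <- voronoi_apl(f, frame = 1L)
    write_tsv(as.data.frame(va),
              file.path(dir, sprintf("voronoi_%s.tsv", label)))
    td <- tilt_distribution(f)
    write_tsv(data.frame(angle_deg = td$angles),
              file.path(dir, sprintf("tilt_%s.tsv", label)))
  }
}

assay_stage <- function(config, inputs, dir) {
  for (nm in c("growth", "lysis"))
    if (is.null(inputs[[nm]]))
      stop_mo("assay stage: missing input `%s`", nm)
  gcs <- read_growth_curves(inputs$growth)
  rates <- do.call(rbind, lapply(names(gcs), function(s) {
    gr <- growth_rate(gcs[[s]], od_window = config$od_window)
    data.frame(sample = s, diet = gr$diet, rate_od_per_h = gr$rate,
               r_squared = gr$r_squared)
  }))
  write_tsv(rates, file.path(dir, "growth_rates.tsv"))
  lf <- lysed_fraction(read_lysis_plate(inputs$lysis),
                       report_at = config$report_at)
  write_tsv(as.data.frame(lf), file.path(dir, "lysed_fractions.tsv"))
  stats <- list()
  if (length(unique(rates$diet)) >= 2L) {
    gcmp <- group_compare(rates$rate_od_per_h, rates$diet)
    stats$growth <- data.frame(assay = "growth_rate", F = gcmp$F, p = gcmp$p)
  }
  if (!all(is.na(lf$diet)) && length(unique(lf$diet)) >= 2L) {
    lcmp <- group_compare(lf$fraction, lf$diet)
    stats$lysis <- data.frame(assay = "lysed_fraction", F = lcmp$F, p = lcmp$p)
  }
  if (length(stats))
    write_tsv(do.call(rbind, stats), file.path(dir, "assay_stats.tsv"))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages with explicit seeds.  A `"simulate"` stage
#' generates all fixtures (isotherm CSVs, a Delta-9-like and a
#' Delta-11-like bilayer as multi-model PDB plus topology YAML, assay
#' CSVs) under `out_dir/inputs`; later stages consume either those or the
#' files named in `config$inputs`.  Outputs are tab-separated tables under
#' `out_dir`, listed with MD5 checksums in `manifest.json` together with
#' the echoed configuration and its hash.  Identical config + inputs give
#' byte-identical outputs.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs
  frames <- NULL
  if ("simulate" %in% config$stages) {
    gdir <- file.path(config$out_dir, "inputs")
    dir.create(gdir, showWarnings = FALSE)
    sim <- simulate_stage(config, gdir)
    inputs <- utils::modifyList(sim$paths, inputs)
    frames <- sim$frames
  }
  if ("isotherm" %in% config$stages)
    isotherm_stage(config, inputs, config$out_dir)
  if ("traj" %in% config$stages)
    traj_stage(config, inputs, config$out_dir, frames = frames)
  if ("assay" %in% config$stages)
    assay_stage(config, inputs, config$out_dir)
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    files = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(config$out_dir, f))))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' End-to-end self-test
#'
#' Generates fixtures, runs every stage on them, and asserts the package's
#' cross-module invariants: condensation/energy ground-truth recovery,
#' S_CD bounds and recovery, Voronoi area conservation, histogram mass
#' conservation, and assay ground-truth recovery.  Stops on the first
#' violated invariant.
#'
#' @param seed Integer seed.
#' @param out_dir Scratch directory (default: a session temp dir).
#' @param generator Generator options forwarded to [run_config()], e.g. a
#'   reduced system size.
#' @return `TRUE` invisibly on success.
#' @export
selftest <- function(seed = 1, out_dir = tempfile("memorder_selftest"),
                     generator = list()) {
  cfg <- run_config(seed = seed, out_dir = out_dir, generator = generator)
  run_pipeline(cfg)

  # ideal-mixing invariant: zero excess -> condensation 0 and dG 0
  p <- seq(0.5, 30, by = 0.5)
  m1 <- isotherm_model(90, 20, 50); m2 <- isotherm_model(45, 25, 38)
  c1 <- gen_pure_isotherm(m1, p); c2 <- gen_pure_isotherm(m2, p)
  truth0 <- mixture_ground_truth(c(2/3, 1/3), 0)
  mix0 <- gen_mixture_isotherm(c1, c2, truth0)
  cc <- condensation(mix0, c1, c2, X1 = 2/3)
  stopifnot(abs(cc$c) < 1e-10)
  dg <- excess_mixing_energy(mix0, c1, c2, X1 = 2/3)
  stopifnot(abs(dg$delta_g) < 1e-8)

  # bilayer invariants on a small system
  fr <- gen_bilayer_frames(synthetic_bilayer_spec(
    n_lipids_per_leaflet = 16, n_frames = 5, seed = seed + 1,
    target_cos2 = 0.6))
  fr <- center_and_assign_leaflets(fr)
  stopifnot(sum(fr$atoms$leaflet[!duplicated(fr$atoms$resid)] == 1) ==
            sum(fr$atoms$leaflet[!duplicated(fr$atoms$resid)] == -1))
  prof <- scd_profile(fr, chain = "sn1")
  stopifnot(all(prof$scd >= -0.5 - 1e-12), all(prof$scd <= 1 + 1e-12))
  zh <- group_z_distribution(fr)
  stopifnot(all(abs(colSums(zh$density) * zh$bin_width - 1) < 1e-9))
  va <- voronoi_apl(fr)
  stopifnot(all(abs(voronoi_totals(va)$rel_error) < 1e-6))

  # assay recovery
  gr <- growth_rate(gen_growth_curve(0.05, od_start = 0.8))
  stopifnot(abs(gr$rate - 0.05) < 1e-12)
  lf <- lysed_fraction(gen_lysis_plate(0.4))
  stopifnot(abs(lf$fraction - 0.4) < 1e-12)
  invisible(TRUE)
}
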