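#' Write a numeric table as TSV with bit-exact round-trip
#'
#' Numbers are serialised with 17 significant digits (`%.17g`), enough for
#' IEEE doubles to round-trip exactly through [read_tsv_table()].
#'
#' @param df a data frame of numeric/logical/character columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path file to read.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config))
    cfg <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    cfg$config_hash <- unname(tools::md5sum(config))
    cfg
  } else if (is.list(config)) {
    config$config_hash <- unname(tools::md5sum(
      textConnection_write(jsonlite::toJSON(config, auto_unbox = TRUE))))
    config
  } else stop("`config` must be a file path or a list")
}

# md5 of a string via a temp file (tools::md5sum wants a file)
textConnection_write <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}

.cfg <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the full coordinate-to-thermodynamics analysis
#'
#' Orchestrates the pipeline on one or more coordinate files: tilt
#' estimation and correction, central-slab cropping, concentration
#' profiles, per-replicate boundary-corrected RDFs, replicate averaging,
#' PMF inversion, effective-PIP pooling across concentration groups,
#' structure factors, Kirkwood-Buff integrals (direct and sub-box with
#' extrapolation) and second virial coefficients.  All defaults in play
#' (g floor, S(q) window, sub-box stride and L fit range) are recorded in
#' the report's `settings` block.
#'
#' The JSON config carries: `inputs` (records with `path`, `format`,
#' optional `label`), `box` (`extents`, optional `origin`),
#' `temperature_K`, optional `molecular_weight_gmol`, and optional
#' per-stage override blocks `tilt_correction` (logical), `crop` (`"auto"`,
#' `[z_lo, z_hi]` or `false`), `rdf` (`bin_width`, `n_bins`), `pmf`
#' (`g_floor`), `sq` (`window`), `kbi` (`stride`, `L_max`, `L`, `cutoff`)
#' and `seed`.
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @param out_dir output directory for the JSON report and TSV tables.
#' @return The report, an object of class `analysis_report`, invisibly.
#' @export
cmd_analyze <- function(config, out_dir = ".") {
  cfg <- .read_config(config)
  if (is.null(cfg$inputs) || NROW(cfg$inputs) < 1)
    stop("config must reference at least one coordinate file")
  inputs <- if (is.data.frame(cfg$inputs)) split(cfg$inputs, seq_len(nrow(cfg$inputs)))
            else cfg$inputs
  box <- .stage("config", box_geometry(unlist(cfg$box$extents),
                                       origin = .cfg(cfg$box, "origin", c(0, 0, 0))))
  temperature <- .cfg(cfg, "temperature_K", 293.15)
  mw <- cfg$molecular_weight_gmol
  seed <- .cfg(cfg, "seed", 1)
  rdf_cfg <- .cfg(cfg, "rdf", list())
  bin_width <- .cfg(rdf_cfg, "bin_width", 0.3)
  n_bins <- .cfg(rdf_cfg, "n_bins", 100)
  g_floor <- .cfg(.cfg(cfg, "pmf", list()), "g_floor", 1e-3)
  window <- .cfg(.cfg(cfg, "sq", list()), "window", "lorch")
  kbi_cfg <- .cfg(cfg, "kbi", list())
  stride <- .cfg(kbi_cfg, "stride", 3)
  L_max <- .cfg(kbi_cfg, "L_max", 50)
  L_list <- kbi_cfg$L
  kbi_cutoff <- .cfg(kbi_cfg, "cutoff", bin_width * n_bins)
  crop_mode <- .cfg(cfg, "crop", "auto")
  do_tilt <- .cfg(cfg, "tilt_correction", TRUE)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  sets <- lapply(inputs, function(inp) {
    .stage("load", {
      if (is.null(inp$path) || !file.exists(inp$path))
        stop(sprintf("input file '%s' does not exist", inp$path))
      load_particles(inp$path, format = .cfg(inp, "format", "csv"), box = box,
                     temperature = temperature, molecular_weight = mw,
                     label = .cfg(inp, "label", "sample"))
    })
  })

  tilt_info <- NULL
  if (isTRUE(do_tilt)) {
    sets <- lapply(sets, function(ps) .stage("tilt", {
      ti <- estimate_tilt(ps)
      tilt_info[[length(tilt_info) + 1]] <<- ti
      apply_tilt_correction(ps, ti)
    }))
  }
  if (!isFALSE(crop_mode)) {
    sets <- lapply(sets, function(ps) .stage("crop", {
      if (is.character(crop_mode) && crop_mode == "auto")
        crop_central_slab(ps)
      else crop_central_slab(ps, crop_mode[1], crop_mode[2])
    }))
  }
  profiles <- lapply(sets, function(ps)
    .stage("concentration", concentration_profile(ps)))

  labels <- vapply(sets, function(ps) ps$label %||% "sample", character(1))
  groups <- split(seq_along(sets), labels)

  per_group <- lapply(names(groups), function(lab) {
    idx <- groups[[lab]]
    frames <- sets[idx]
    rdf <- .stage("rdf", compute_rdf_frames(frames, bin_width = bin_width,
                                            n_bins = n_bins))
    pmf <- .stage("pmf", pmf_from_rdf(rdf, g_floor = g_floor))
    sq <- .stage("sq", structure_factor(rdf, window = window))
    kd <- .stage("kbi", kbi_direct(rdf, cutoff = kbi_cutoff))
    scan <- .stage("kbi", kbi_subbox(frames, L = L_list, stride = stride))
    kext <- .stage("kbi", kbi_extrapolate(scan, L_max = L_max, seed = seed))
    list(label = lab, rdf = rdf, pmf = pmf, sq = sq, kbi_direct = kd,
         subbox = scan, kbi_subbox = kext,
         density = mean(vapply(frames, number_density, numeric(1))))
  })
  names(per_group) <- names(groups)

  pip_res <- .stage("pip", effective_pip(lapply(per_group, `[[`, "pmf")))
  b22_pip <- .stage("b22", b22_from_potential(pip_res$pip,
                                              cutoff = kbi_cutoff))
  s0_points <- vapply(per_group, function(g)
    s_zero(G_inf = g$kbi_subbox$G_inf, density = g$density), numeric(1))
  b22_slope <- if (length(per_group) >= 2)
    .stage("b22", b22_from_s0_slope(
      vapply(per_group, `[[`, numeric(1), "density"), s0_points))
  else NULL

  settings <- list(bin_width = bin_width, n_bins = n_bins,
                   g_floor = g_floor, sq_window = window,
                   subbox_stride = stride, subbox_L_max = L_max,
                   kbi_cutoff = kbi_cutoff, seed = seed,
                   crop = crop_mode, tilt_correction = do_tilt)
  message(sprintf(
    "settings in effect: g_floor=%g, window=%s, stride=%g nm, L_max=%g nm, cutoff=%g nm",
    g_floor, window, stride, L_max, kbi_cutoff))

  report <- structure(list(
    provenance = list(
      inputs = vapply(inputs, function(i) i$path, character(1)),
      config_hash = cfg$config_hash, seed = seed,
      package_version = as.character(utils::packageVersion("tomopip"))),
    settings = settings,
    concentration = lapply(profiles, function(p) list(
      plateau_range = p$plateau_range,
      median_density_nm3 = median(p$number_density),
      median_mg_ml = if (!is.null(p$mass_concentration))
        median(p$mass_concentration) else NA_real_)),
    tilt = lapply(tilt_info, function(t) list(
      angle_x = t$angle_x, angle_y = t$angle_y,
      residual_rms = t$residual_rms, slab_like = t$slab_like)),
    groups = lapply(per_group, function(g) list(
      label = g$label, density_nm3 = g$density,
      G_inf_direct = g$kbi_direct$G_inf,
      G_inf_subbox = g$kbi_subbox$G_inf,
      G_inf_subbox_stderr = g$kbi_subbox$stderr,
      subbox_fit = g$kbi_subbox$fit[c("slope", "r_squared")],
      s_zero = s_zero(G_inf = g$kbi_subbox$G_inf, density = g$density))),
    pip = list(max_deviation = pip_res$max_deviation, flag = pip_res$flag,
               threshold = pip_res$threshold),
    b22 = list(from_pip_nm3 = b22_pip,
               from_pip_mol_ml_g2 = if (!is.null(mw))
                 b22_to_mol_ml_g2(b22_pip, mw) else NA_real_,
               from_s0_slope_nm3 = if (!is.null(b22_slope)) b22_slope$b22
                 else NA_real_,
               from_s0_slope_stderr = if (!is.null(b22_slope))
                 b22_slope$stderr else NA_real_)),
    class = "analysis_report")

  for (g in per_group) {
    tag <- gsub("[^A-Za-z0-9_.-]", "_", g$label)
    write_tsv_table(data.frame(
      r_nm = g$rdf$r_centers, g = g$rdf$g,
      g_std = g$rdf$replicate_std %||% rep(NA_real_, length(g$rdf$g)),
      W_kT = g$pmf$value, valid = g$pmf$valid),
      file.path(out_dir, paste0("rdf_", tag, ".tsv")))
    write_tsv_table(data.frame(
      q_inv_nm = g$sq$q, S = g$sq$S,
      reliable = g$sq$q >= g$sq$q_min_reliable),
      file.path(out_dir, paste0("sq_", tag, ".tsv")))
    write_tsv_table(data.frame(
      L_nm = g$subbox$L, SV_inv_nm = g$subbox$SV,
      G_eff_nm3 = g$subbox$G_eff, n_subboxes = g$subbox$n_subboxes),
      file.path(out_dir, paste0("subbox_", tag, ".tsv")))
  }
  write_tsv_table(data.frame(
    r_nm = pip_res$pip$r, U_kT = pip_res$pip$value,
    valid = pip_res$pip$valid),
    file.path(out_dir, "pip.tsv"))
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (g in x$groups)
    cat(sprintf("  [%s] rho = %.4g nm^-3, G_direct = %.4g, G_subbox = %.4g +/- %.3g nm^3, S(0) = %.4g\n",
                g$label, g$density_nm3, g$G_inf_direct, g$G_inf_subbox,
                g$G_inf_subbox_stderr, g$s_zero))
  cat(sprintf("  PIP spread %.3g kT (flag: %s); B22(PIP) = %.4g nm^3\n",
              x$pip$max_deviation, x$pip$flag, x$b22$from_pip_nm3))
  invisible(x)
}

#' Generate synthetic coordinate files from a simulation config
#'
#' Wraps the Monte Carlo generator: runs the configured fluid and writes
#' one coordinate file per frame plus a `manifest.json` recording the
#' files, the ground-truth potential and the seed.  Config fields:
#' `potential` (`kind`, `sigma`, `epsilon`, `kappa`, `well_width`), `box`
#' (`extents`), `n_particles`, `temperature_K`, `n_sweeps_equil`,
#' `n_frames`, `sample_every`, `max_displacement`, `seed`, `format`.
#' With `potential.kind = "ideal"` and `ensemble = "grand"` or
#' `"canonical"` the Poisson sampler is used instead.
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @param out_dir output directory.
#' @return The manifest list, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  cfg <- .read_config(config)
  box <- .stage("config", box_geometry(unlist(cfg$box$extents),
                                       periodic = TRUE))
  pot_cfg <- .cfg(cfg, "potential", list(kind = "ideal"))
  pot <- .stage("config", do.call(potential_spec, pot_cfg[
    intersect(names(pot_cfg), c("kind", "sigma", "epsilon", "kappa",
                                "well_width"))]))
  n <- .cfg(cfg, "n_particles", 1000)
  n_frames <- .cfg(cfg, "n_frames", 10)
  seed <- .cfg(cfg, "seed", 1)
  fmt <- .cfg(cfg, "format", "csv")
  temperature <- .cfg(cfg, "temperature_K", 293.15)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ens <- .cfg(cfg, "ensemble", NULL)
  if (pot$kind == "ideal" && !is.null(ens)) {
    frames <- sample_poisson(box, n = n, n_frames = n_frames, ensemble = ens,
                             seed = seed, temperature = temperature)
    if (n_frames == 1) frames <- list(frames)
    acc <- 1
  } else {
    mc <- .stage("simulate", run_mc(
      pot, box, n,
      n_sweeps_equil = .cfg(cfg, "n_sweeps_equil", 500),
      n_frames = n_frames,
      sample_every = .cfg(cfg, "sample_every", 10),
      max_displacement = .cfg(cfg, "max_displacement", 3),
      seed = seed, temperature = temperature))
    frames <- mc$frames
    acc <- mc$acceptance_rate
  }
  files <- vapply(seq_along(frames), function(i) {
    f <- file.path(out_dir, sprintf("frame_%04d.%s", i, fmt))
    write_particles(frames[[i]], f, format = fmt)
    basename(f)
  }, character(1))
  manifest <- list(files = files, potential = unclass(pot)[
    c("kind", "sigma", "epsilon", "kappa", "well_width")],
    box_extents = box$extents, n_particles = n, seed = seed,
    acceptance_rate = acc,
    package_version = as.character(utils::packageVersion("tomopip")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
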