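#' Default pipeline configuration
#'
#' Nested list with one namespace per stage; every threshold and default
#' named by the analysis modules appears here so a run can be reproduced
#' from its resolved-config snapshot alone. Unknown keys in a user config
#' are rejected by [run_pipeline()].
#'
#' @param seed master RNG seed for the run.
#' @param out_dir output directory.
#' @return Configuration list.
#' @export
default_config <- function(seed = 1, out_dir = "posidonia_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, eddyflux = TRUE, rates = TRUE,
                  screen = TRUE, imaging = TRUE, tpm = TRUE),
    eddyflux = list(
      true_flux = 2, lag_s = 2.5, tilt_deg = 5, spike_count = 5,
      duration_s = 7200, fs_vel = 16, fs_o2 = 4, snr = 5,
      cutoff_s = 300, k_mad = 6, window = 9, max_lag_s = 10,
      jump_k = 50, burst_s = 3600
    ),
    rates = list(
      n_plants = 3, pool_atpct = 5.4, na_mean = 2.4, na_sd = 0.3,
      n_pieces = 8, t = 1, root_rate = 0.5, rhizome_rate = 0.05,
      leaf_rate = 0.05, classification_threshold = 0.01
    ),
    screen = list(
      n_samples = 6, min_frac = 0.10, total_reads = 10000,
      organellar_fracs = c(0.05, 0.15, 0.20, 0.30, 0.25, 0.40),
      symbiont_fracs = c(0.01, 0.05, 0.10, 0.20, 0.02, 0.15)
    ),
    imaging = list(
      size = 128, tissue_radius = 55, n_cells = 12, cell_radius = 3,
      cell_atpct = 5, tissue_atpct = 1, counts_per_px = 2000,
      n_planes = 10, threshold_frac = 0.01, min_counts = 100,
      px_size = 0.1, max_shift = 5
    ),
    tpm = list(n_features = 50, n_samples = 2,
               housekeeping = default_housekeeping_genes())
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base)) {
      stop(structure(class = c("posidonia_config_error", "error", "condition"),
                     list(message = sprintf("unknown configuration key: %s%s",
                                            path, k),
                          call = NULL)))
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_error <- function(msg) {
  stop(structure(class = c("posidonia_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

count_mat_to_tiff <- function(path, planes) {
  tiff::writeTIFF(lapply(planes, function(m) m / 65535), path,
                  bits.per.sample = 16, compression = "none")
}

tiff_to_count_array <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- round(pages[[p]] * 65535)
  arr
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — `simulate` (synthetic
#' inputs with truth sidecars), `eddyflux`, `rates`, `screen`, `imaging`,
#' `tpm` — reading each stage's inputs from files in `out_dir` and writing
#' per-stage outputs plus a machine-readable run manifest (package version,
#' seed, resolved configuration, per-file MD5 checksums). A stage failure
#' aborts the downstream stages with a typed `posidonia_stage_error`;
#' outputs already written are retained. All randomness derives from the
#' configured seed, so a rerun with the same resolved configuration
#' reproduces every output bit-identically.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a YAML file with the same structure; partial configs are merged
#'   into the defaults, unknown keys are rejected.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      config_error(sprintf("configuration file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    log("[%s] start", name)
    res <- tryCatch(fun(), error = function(e) {
      if (inherits(e, "posidonia_config_error")) stop(e)
      stop(structure(class = c("posidonia_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s",
                                            name, conditionMessage(e)),
                          call = NULL)))
    })
    log("[%s] done", name)
    res
  }
  p <- function(f) file.path(cfg$out_dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) {
      config_error(sprintf("required input missing: %s", p(f)))
    }
    p(f)
  }

  run_stage("simulate", function() {
    ec <- cfg$eddyflux
    rec <- gen_ec_timeseries(
      ec_truth(ec$true_flux, ec$lag_s, ec$tilt_deg, ec$spike_count,
               seed = cfg$seed),
      duration_s = ec$duration_s, fs_vel = ec$fs_vel, fs_o2 = ec$fs_o2,
      snr = ec$snr)
    utils::write.csv(rec$velocity, p("ec_velocity.csv"), row.names = FALSE)
    utils::write.csv(rec$scalar, p("ec_scalar.csv"), row.names = FALSE)

    rt <- cfg$rates
    tabs <- lapply(seq_len(rt$n_plants), function(i) {
      tr <- rate_truth(
        rates = c(root = rt$root_rate * i / rt$n_plants,
                  rhizome = rt$rhizome_rate, leaf = rt$leaf_rate),
        pool_atpct = rt$pool_atpct, na_mean = rt$na_mean, na_sd = rt$na_sd,
        n_pieces = rt$n_pieces, t = rt$t, seed = cfg$seed + i)
      gen_tissue_isotopes(tr, plant_id = sprintf("plant_%d", i),
                          control_id = sprintf("control_%d", i))
    })
    utils::write.csv(do.call(rbind, lapply(tabs, as.data.frame)),
                     p("isotopes.csv"), row.names = FALSE)

    sc <- cfg$screen
    amp <- gen_amplicon_table(sc$n_samples, sc$organellar_fracs,
                              sc$symbiont_fracs, seed = cfg$seed,
                              total_reads = sc$total_reads)
    utils::write.table(as.data.frame(amp), p("amplicon.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    im <- cfg$imaging
    itr <- image_truth(size = im$size, tissue_radius = im$tissue_radius,
                       n_cells = im$n_cells, cell_radius = im$cell_radius,
                       cell_atpct = im$cell_atpct,
                       tissue_atpct = im$tissue_atpct,
                       counts_per_px = im$counts_per_px,
                       n_planes = im$n_planes, seed = cfg$seed)
    cis <- gen_correlative_images(itr, px_size = im$px_size)
    fl <- cis$fluor
    fluor_arr <- array(0, dim = c(im$size, im$size, 3))
    fluor_arr[, , 1] <- fl$fish; fluor_arr[, , 2] <- fl$autofluor
    fluor_arr[, , 3] <- fl$dapi
    tiff::writeTIFF(pmin(fluor_arr / 65535, 1), p("fluorescence.tif"),
                    bits.per.sample = 16, compression = "none")
    for (s in names(cis$stack$species)) {
      planes <- lapply(seq_len(cis$stack$n_planes),
                       function(q) cis$stack$species[[s]][, , q])
      count_mat_to_tiff(p(sprintf("sims_%s.tif", s)), planes)
    }
    jsonlite::write_json(list(
      ec_truth = unclass(rec$truth),
      rate_truth = lapply(tabs, function(x) {
        tr <- attr(x, "truth")
        list(rates = as.list(tr$rates), pool_atpct = tr$pool_atpct)
      }),
      image_truth = list(cell_atpct = itr$cell_atpct,
                         tissue_atpct = itr$tissue_atpct,
                         n_cells = nrow(itr$centers)),
      amplicon_truth = attr(amp, "truth")
    ), p("truth.json"), auto_unbox = TRUE, digits = NA)

    counts <- gen_count_table(cfg$tpm$n_features, cfg$tpm$n_samples,
                              seed = cfg$seed)
    utils::write.table(counts, p("counts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, "ec_velocity.csv", "ec_scalar.csv",
                  "isotopes.csv", "amplicon.tsv", "fluorescence.tif",
                  sprintf("sims_%s.tif", names(cis$stack$species)),
                  "truth.json", "counts.tsv")
  })

  run_stage("eddyflux", function() {
    ec <- cfg$eddyflux
    vel <- utils::read.csv(need("ec_velocity.csv"))
    scal <- utils::read.csv(need("ec_scalar.csv"))
    rec <- structure(list(velocity = vel, scalar = scal,
                          fs_vel = ec$fs_vel, fs_o2 = ec$fs_o2),
                     class = "ec_recording")
    res <- ec_process(rec, cutoff_s = ec$cutoff_s, k_mad = ec$k_mad,
                      window = ec$window, max_lag_s = ec$max_lag_s,
                      jump_k = ec$jump_k, burst_s = ec$burst_s)
    utils::write.csv(as.data.frame(res$bursts), p("ec_bursts.csv"),
                     row.names = FALSE)
    d <- res$daily
    utils::write.csv(data.frame(net_daily_o2 = d$net_daily,
                                net_daily_co2 = d$co2_daily,
                                sd_propagated = d$sd_propagated,
                                day_mean = d$day_mean,
                                night_mean = d$night_mean,
                                n_day = d$n_day, n_night = d$n_night),
                     p("ec_daily.csv"), row.names = FALSE)
    log("[eddyflux] lag %.3f s, %d spikes replaced, truncation=%s",
        res$lag_s, res$spike_count, as.character(res$truncation$jump_detected))
    outputs <<- c(outputs, "ec_bursts.csv", "ec_daily.csv")
  })

  run_stage("rates", function() {
    rt <- cfg$rates
    tab <- utils::read.csv(need("isotopes.csv"))
    rates <- compute_rates(tab, pool_enrichment(rt$pool_atpct))
    utils::write.csv(as.data.frame(rates), p("rates.csv"), row.names = FALSE)
    roots <- rates[rates$tissue == "root", ]
    plants <- do.call(rbind, lapply(split(roots, roots$plant_id), function(g) {
      data.frame(plant_id = g$plant_id[1],
                 mean_root_rate = mean(g$rate),
                 classification = classify_plant(
                   g$rate, avg_lod = rt$classification_threshold))
    }))
    utils::write.csv(plants, p("plants.csv"), row.names = FALSE)
    outputs <<- c(outputs, "rates.csv", "plants.csv")
  })

  run_stage("screen", function() {
    sc <- cfg$screen
    tab <- taxon_count_table(utils::read.table(need("amplicon.tsv"),
                                               header = TRUE, sep = "\t"))
    qc <- apply_qc(tab, min_frac = sc$min_frac)
    ratio <- symbiont_organellar_ratio(tab)
    rep <- merge(qc$report, ratio[, c("sample_id", "ratio")], by = "sample_id")
    utils::write.csv(rep, p("screen_report.csv"), row.names = FALSE)
    log("[screen] excluded %d of %d samples", nrow(qc$excluded),
        nrow(qc$report))
    outputs <<- c(outputs, "screen_report.csv")
  })

  run_stage("imaging", function() {
    im <- cfg$imaging
    fl <- tiff::readTIFF(need("fluorescence.tif")) * 65535
    n14 <- tiff_to_count_array(need("sims_12C14N.tif"))
    n15 <- tiff_to_count_array(need("sims_12C15N.tif"))
    stack <- ion_count_stack(list(`12C14N` = n14, `12C15N` = n15))
    acc <- accumulate_planes(stack, max_shift = im$max_shift,
                             drift = matrix(0L, dim(n14)[3], 2))
    ri <- ratio_to_atpct(acc$accumulated$`12C15N`, acc$accumulated$`12C14N`,
                         min_counts = im$min_counts, valid = acc$valid)
    tissue <- binarize_tissue(fl[, , 2], im$threshold_frac)
    cells <- detect_cells(fl[, , 1], fl[, , 3], im$threshold_frac)
    masks <- mask_set(tissue, cells)
    enr <- masked_mean_enrichment(ri, masks)
    utils::write.csv(data.frame(atpct_cells = enr$atpct_cells,
                                atpct_tissue = enr$atpct_tissue,
                                n_cell_px = enr$n_cell_px,
                                n_tissue_px = enr$n_tissue_px),
                     p("enrichment.csv"), row.names = FALSE)
    na_at <- atpct_natural()
    mb <- transfer_mass_balance(
      integrate_area(tissue & !cells, im$px_size),
      max(enr$atpct_tissue - na_at, 0),
      integrate_area(cells, im$px_size),
      max(enr$atpct_cells - na_at, 0))
    jsonlite::write_json(unclass(mb), p("mass_balance.json"),
                         auto_unbox = TRUE, digits = NA)
    tiff::writeTIFF(matrix(as.numeric(tissue), nrow(tissue)),
                    p("tissue_mask.tif"), bits.per.sample = 8,
                    compression = "none")
    tiff::writeTIFF(matrix(as.numeric(cells), nrow(cells)),
                    p("cell_mask.tif"), bits.per.sample = 8,
                    compression = "none")
    outputs <<- c(outputs, "enrichment.csv", "mass_balance.json",
                  "tissue_mask.tif", "cell_mask.tif")
  })

  run_stage("tpm", function() {
    counts <- utils::read.table(need("counts.tsv"), header = TRUE, sep = "\t")
    tt <- housekeeping_normalize(tpm(counts), hk_ids = cfg$tpm$housekeeping)
    utils::write.table(as.data.frame(tt), p("tpm.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, "tpm.tsv")
  })

  writeLines(log_lines, p("run_log.txt"))
  files <- file.path(cfg$out_dir, outputs)
  manifest <- list(
    package = "posidoniaSIP",
    version = as.character(utils::packageVersion("posidoniaSIP")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg,
    outputs = data.frame(file = outputs,
                         md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Validate delimited input files against column schemas
#'
#' Light-weight structural validation: required columns present, numeric
#' columns numeric, and value constraints (non-negative counts, positive
#' lengths and times). Violations are reported, not raised.
#'
#' @param paths named character vector of file paths; names select the
#'   schema (`count_table`, `isotope_table`, `amplicon_table`,
#'   `ec_velocity`, `ec_scalar`).
#' @param schemas schema definitions; defaults to [builtin_schemas()].
#' @return Data frame with columns `file`, `schema`, `violation` (zero rows
#'   when everything passes).
#' @export
validate_inputs <- function(paths, schemas = builtin_schemas()) {
  out <- list()
  add <- function(file, schema, msg) {
    out[[length(out) + 1L]] <<- data.frame(file = file, schema = schema,
                                           violation = msg)
  }
  for (i in seq_along(paths)) {
    nm <- names(paths)[i]; f <- paths[i]
    sc <- schemas[[nm]]
    if (is.null(sc)) {
      add(f, nm, "no schema of this name")
      next
    }
    if (!file.exists(f)) {
      add(f, nm, "file does not exist")
      next
    }
    sep <- if (grepl("\\.tsv$", f)) "\t" else ","
    df <- tryCatch(utils::read.table(f, header = TRUE, sep = sep),
                   error = function(e) NULL)
    if (is.null(df)) {
      add(f, nm, "unreadable as a delimited table")
      next
    }
    miss <- setdiff(sc$required, names(df))
    if (length(miss)) {
      add(f, nm, paste("missing column(s):", paste(miss, collapse = ", ")))
      next
    }
    for (chk in names(sc$checks)) {
      msg <- sc$checks[[chk]](df)
      if (!is.null(msg)) add(f, nm, msg)
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(file = character(0), schema = character(0),
               violation = character(0))
  }
}

#' @rdname validate_inputs
#' @export
builtin_schemas <- function() {
  list(
    count_table = list(
      required = c("feature_id", "sample_id", "count", "length_kb"),
      checks = list(
        counts = function(df) if (any(df$count < 0)) "negative counts",
        lengths = function(df) if (any(df$length_kb <= 0)) "non-positive feature lengths"
      )
    ),
    isotope_table = list(
      required = c("plant_id", "tissue", "delta15N", "n_content",
                   "dry_weight", "labelled", "t"),
      checks = list(
        t = function(df) if (any(df$t[df$labelled] <= 0)) "non-positive incubation time on labelled rows",
        mass = function(df) if (any(df$dry_weight <= 0)) "non-positive dry weights"
      )
    ),
    amplicon_table = list(
      required = c("sample_id", "taxon_id", "count", "category"),
      checks = list(
        counts = function(df) if (any(df$count < 0)) "negative counts",
        category = function(df) {
          bad <- setdiff(unique(df$category),
                         c("bacterial", "organellar", "symbiont"))
          if (length(bad)) paste("unknown categories:", paste(bad, collapse = ", "))
        }
      )
    ),
    ec_velocity = list(
      required = c("time", "u", "v", "w"),
      checks = list(
        time = function(df) if (any(diff(df$time) <= 0)) "time not strictly increasing"
      )
    ),
    ec_scalar = list(
      required = c("time", "c"),
      checks = list(
        time = function(df) if (any(diff(df$time) <= 0)) "time not strictly increasing"
      )
    )
  )
}
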