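# ---- per-subject cochlear pipeline ----------------------------------------

#' Run the cochlear analysis pipeline for one subject
#'
#' Full signal path per ear: epoch extraction (when continuous recordings are
#' present), automated saturation rejection on the raw epochs, zero-phase
#' 500 Hz high-pass, bandpass bank with Hilbert envelopes, induced and evoked
#' modulation spectra per attention condition, spectral parameterization of
#' the band-averaged spectra, peak validation (Dixon's Q), AMI maps and
#' pooled AMI per ear-specific modulation range, and optionally all
#' quantities recomputed within reaction-time median-split halves.
#'
#' @param subject A [simulate_subject()] result (or a compatible list with
#'   `recordings`/`epochs` and `trial_table`).
#' @param scfg A [study_config()].
#' @param ears Ears to analyze.
#' @param evoked Compute evoked spectra and phases.
#' @param rt_split Recompute induced quantities within fast/slow halves.
#' @return A list of class `"subject_analysis"`; per ear: spectra, fits,
#'   peaks, validations, AMI maps, pooled AMI, and rejection log.
#' @export
analyze_subject <- function(subject, scfg = study_config(),
                            ears = c("left", "right"),
                            evoked = TRUE, rt_split = FALSE) {
  validate_study_config(scfg)
  gen <- scfg$generator
  tt <- subject$trial_table
  out <- list(subject_id = subject$subject_id, ears = list())
  for (ear in ears) {
    if (!is.null(subject$recordings)) {
      ep <- extract_epochs(subject$recordings[[ear]], tt,
                           duration = gen$epoch_duration)
    } else {
      ep <- subject$epochs[[ear]]
    }
    ep <- reject_saturation(ep, clip_fraction = scfg$clip_fraction,
                            min_run_ms = scfg$min_run_ms)
    # zero-phase 500 Hz high-pass fused into the frequency-domain bank
    bank <- bandpass_bank(ep, low = gen$carrier_band[1],
                          high = gen$carrier_band[2],
                          half_width = scfg$half_width,
                          n_windows = scfg$n_windows,
                          envelope_sr = scfg$envelope_sr,
                          highpass = list(cutoff = 500, order = 6))
    res <- list(rejected = ep$rejected, n_trials = nrow(ep$data))
    pool_range <- if (ear == "left") scfg$pool_left else scfg$pool_right

    spec_of <- function(idx, mode) {
      b <- subset_bands(bank, idx)
      fun <- if (mode == "induced") induced_mod_spectrum else evoked_mod_spectrum
      fun(b, window = scfg$window, mod_range = scfg$mod_range,
          pad_step = scfg$pad_freq_step)
    }
    analyze_group <- function(idx_a, idx_v, mode) {
      sa <- spec_of(idx_a, mode)
      sv <- spec_of(idx_v, mode)
      grp <- list(spectrum_a = sa, spectrum_v = sv,
                  ami = compute_ami(sa, sv))
      grp$pooled_ami <- pool_ami(grp$ami, band_range = gen$carrier_band,
                                 mod_range = pool_range)
      for (cond in c("a", "v")) {
        sp <- band_average(grp[[paste0("spectrum_", cond)]])
        fit <- fit_spectral_model(sp$power, sp$freqs,
                                  freq_range = scfg$fit_range,
                                  max_peaks = scfg$max_peaks,
                                  peak_threshold = scfg$peak_threshold,
                                  min_peak_height = scfg$min_peak_height)
        pk <- primary_low_freq_peak(fit, limit = scfg$peak_limit)
        grp[[paste0("fit_", cond)]] <- fit
        grp[[paste0("peak_", cond)]] <- pk
        grp[[paste0("q_", cond)]] <- validate_fit_peak(fit, limit = scfg$peak_limit)
      }
      grp
    }

    cond <- ep$trial_info$condition
    ia <- which(cond == "auditory")
    iv <- which(cond == "visual")
    res$induced <- analyze_group(ia, iv, "induced")
    if (evoked) {
      res$evoked <- analyze_group(ia, iv, "evoked")
      for (cc in c("a", "v")) {
        pk <- res$evoked[[paste0("peak_", cc)]]
        if (pk$found) {
          res$evoked[[paste0("phase_", cc)]] <- extract_evoked_phase(
            res$evoked[[paste0("spectrum_", cc)]],
            band_range = gen$carrier_band, peak_freq = pk$cf)
        } else {
          res$evoked[[paste0("phase_", cc)]] <- NA_real_
        }
      }
    }
    if (rt_split) {
      split_tt <- median_split(ep$trial_info)
      for (sp in c("fast", "slow")) {
        ja <- which(cond == "auditory" & split_tt$rt_group == sp)
        jv <- which(cond == "visual" & split_tt$rt_group == sp)
        res[[paste0("induced_", sp)]] <- analyze_group(ja, jv, "induced")
      }
    }
    out$ears[[ear]] <- res
  }
  class(out) <- "subject_analysis"
  out
}

#' Validate the primary spectral peak with Dixon's Q
#'
#' Pools the aperiodic-flattened log power at the primary peak with the
#' flattened power at non-peak frequencies (bins of the fit range subsampled
#' to ~1 Hz spacing and farther than 1.5 bandwidths from every fitted peak)
#' and applies [dixon_q_test()]. The 1 Hz subsampling keeps the pooled count
#' within the test's 3-30 applicability window.
#'
#' @param fit A `"spectral_fit"`.
#' @param limit Primary-peak frequency limit (Hz).
#' @param spacing Non-peak subgrid spacing (Hz).
#' @param exclusion Peak exclusion distance in bandwidths.
#' @return A `"peak_validation"` (with `q_applicable = FALSE` when the fit
#'   has no primary peak).
#' @export
validate_fit_peak <- function(fit, limit = 11, spacing = 1, exclusion = 1.5) {
  pk <- primary_low_freq_peak(fit, limit = limit)
  flat <- fit$log_power - (fit$offset - fit$exponent * log10(fit$freqs))
  if (!pk$found) {
    out <- dixon_q_test(0, numeric(0))
    out$q_applicable <- FALSE
    return(out)
  }
  grid <- seq(ceiling(fit$freq_range[1]), floor(fit$freq_range[2]),
              by = spacing)
  idx <- vapply(grid, function(g) which.min(abs(fit$freqs - g)), integer(1))
  idx <- unique(idx)
  far <- rep(TRUE, length(idx))
  for (k in seq_len(nrow(fit$peaks))) {
    far <- far & abs(fit$freqs[idx] - fit$peaks$cf[k]) >
      exclusion * fit$peaks$bw[k]
  }
  peak_bin <- which.min(abs(fit$freqs - pk$cf))
  dixon_q_test(flat[peak_bin], flat[idx[far]])
}

# ---- group-level statistics ------------------------------------------------

#' Group statistics over a cohort of subject analyses
#'
#' Aggregates per-subject cochlear results into the group-level battery:
#' peak-frequency and slope summaries with uniformity tests, Dixon's-Q
#' success proportion with an exact binomial test, pooled-AMI one-tailed t
#' tests (FDR corrected across ears) for induced and evoked spectra, the
#' interaural comparison, circular common-median tests on evoked phases, and
#' when reaction-time splits are present the 2x2x2 / 2x2 repeated-measures
#' ANOVAs.
#'
#' @param analyses List of `"subject_analysis"` objects.
#' @param scfg The [study_config()] used.
#' @param ks_support Support interval (Hz) for the peak-frequency uniformity
#'   test.
#' @return A nested list of class `"group_stats"`.
#' @export
cohort_group_stats <- function(analyses, scfg = study_config(),
                               ks_support = c(1, 11)) {
  ears <- names(analyses[[1]]$ears)
  modes <- intersect(c("induced", "evoked"), names(analyses[[1]]$ears[[1]]))
  get_vec <- function(mode, ear, field, sub = NULL) {
    vapply(analyses, function(a) {
      x <- a$ears[[ear]][[mode]]
      if (!is.null(sub)) x <- x[[sub]]
      val <- x[[field]]
      if (is.null(val)) NA_real_ else as.numeric(val)
    }, numeric(1))
  }
  out <- list(ears = ears, n_subjects = length(analyses))
  for (mode in modes) {
    mo <- list()
    q_success <- 0L
    q_tested <- 0L
    for (ear in ears) {
      em <- list()
      for (cc in c("a", "v")) {
        cf <- vapply(analyses, function(a) {
          pk <- a$ears[[ear]][[mode]][[paste0("peak_", cc)]]
          if (pk$found) pk$cf else NA_real_
        }, numeric(1))
        slope <- vapply(analyses, function(a) {
          a$ears[[ear]][[mode]][[paste0("fit_", cc)]]$exponent
        }, numeric(1))
        qs <- lapply(analyses, function(a) a$ears[[ear]][[mode]][[paste0("q_", cc)]])
        applicable <- vapply(qs, `[[`, logical(1), "q_applicable")
        sig <- vapply(qs, `[[`, logical(1), "q_significant")
        q_success <- q_success + sum(sig[applicable])
        q_tested <- q_tested + sum(applicable)
        cfv <- cf[!is.na(cf)]
        em[[cc]] <- list(
          peak_freq_mean = mean(cfv), peak_freq_sd = stats::sd(cfv),
          n_with_peak = length(cfv),
          slope_mean = mean(slope), slope_sd = stats::sd(slope),
          ks_uniformity = if (length(cfv) >= 3) {
            ks_uniformity_test(pmin(pmax(cfv, ks_support[1]), ks_support[2]),
                               ks_support)
          } else NULL
        )
      }
      pooled <- get_vec(mode, ear, "pooled_ami")
      em$pooled_ami_mean <- mean(pooled)
      em$pooled_ami_se <- stats::sd(pooled) / sqrt(length(pooled))
      em$ami_t <- group_t_test(pooled, tail = "greater")
      em$pooled_ami <- pooled
      mo[[ear]] <- em
    }
    # FDR across ears for the pooled-AMI tests
    pr <- vapply(ears, function(e) mo[[e]]$ami_t$p_value, numeric(1))
    fdr <- fdr_correct(pr, q = scfg$fdr_q)
    for (i in seq_along(ears)) mo[[ears[i]]]$ami_t$p_fdr <- fdr$p_adjusted[i]
    if (length(ears) == 2) {
      mo$interaural_t <- group_t_test(mo[[ears[1]]]$pooled_ami,
                                      mo[[ears[2]]]$pooled_ami, tail = "two")
    }
    mo$dixon_q <- list(successes = q_success, tested = q_tested,
                       proportion = if (q_tested > 0) q_success / q_tested else NA,
                       binomial = if (q_tested > 0) {
                         binomial_proportion_test(q_success, q_tested)
                       } else NULL)
    out[[mode]] <- mo
  }

  if ("evoked" %in% modes && length(ears) == 2) {
    ph <- function(ear, cc) {
      vapply(analyses, function(a) a$ears[[ear]]$evoked[[paste0("phase_", cc)]],
             numeric(1))
    }
    la <- ph(ears[1], "a"); lv <- ph(ears[1], "v")
    ra <- ph(ears[2], "a"); rv <- ph(ears[2], "v")
    ok <- stats::complete.cases(la, lv, ra, rv)
    if (sum(ok) >= 5) {
      ear_test <- circ_common_median_test(c(la[ok], lv[ok]), c(ra[ok], rv[ok]))
      mod_test <- circ_common_median_test(c(la[ok], ra[ok]), c(lv[ok], rv[ok]))
      pf <- fdr_correct(c(ear_test$p_value, mod_test$p_value), q = scfg$fdr_q)
      ear_test$p_fdr <- pf$p_adjusted[1]
      mod_test$p_fdr <- pf$p_adjusted[2]
      out$evoked_phase <- list(ear = ear_test, modality = mod_test)
    }
  }

  # reaction-time split ANOVAs (2x2x2 on peak frequency and slope, 2x2 on AMI)
  if ("induced_fast" %in% names(analyses[[1]]$ears[[1]]) && length(ears) == 2) {
    cells <- expand.grid(ear = ears, rt = c("fast", "slow"),
                         condition = c("a", "v"), stringsAsFactors = FALSE)
    val_mat <- function(field) {
      sapply(seq_len(nrow(cells)), function(j) {
        mode <- paste0("induced_", cells$rt[j])
        vapply(analyses, function(a) {
          x <- a$ears[[cells$ear[j]]][[mode]]
          if (field == "peak") {
            pk <- x[[paste0("peak_", cells$condition[j])]]
            if (pk$found) pk$cf else NA_real_
          } else if (field == "slope") {
            x[[paste0("fit_", cells$condition[j])]]$exponent
          } else {
            x$pooled_ami
          }
        }, numeric(1))
      })
    }
    f3 <- list(ear = cells$ear, rt = cells$rt, condition = cells$condition)
    pk_m <- val_mat("peak")
    pk_m[is.na(pk_m)] <- mean(pk_m, na.rm = TRUE)
    out$rt_anova_peak <- rm_anova(pk_m, f3)
    out$rt_anova_slope <- rm_anova(val_mat("slope"), f3)
    ami_cells <- cells[cells$condition == "a", c("ear", "rt")]
    ami_m <- sapply(seq_len(nrow(ami_cells)), function(j) {
      mode <- paste0("induced_", ami_cells$rt[j])
      vapply(analyses, function(a) a$ears[[ami_cells$ear[j]]][[mode]]$pooled_ami,
             numeric(1))
    })
    out$rt_anova_ami <- rm_anova(ami_m, list(ear = ami_cells$ear,
                                             rt = ami_cells$rt))
    rt_t <- list()
    for (ear in ears) {
      for (sp in c("fast", "slow")) {
        pooled <- vapply(analyses, function(a) {
          a$ears[[ear]][[paste0("induced_", sp)]]$pooled_ami
        }, numeric(1))
        rt_t[[paste0(ear, "_", sp)]] <- group_t_test(pooled, tail = "greater")
      }
    }
    pv <- vapply(rt_t, function(x) x$p_value, numeric(1))
    pf <- fdr_correct(pv, q = scfg$fdr_q)
    for (i in seq_along(rt_t)) rt_t[[i]]$p_fdr <- pf$p_adjusted[i]
    out$rt_ami_t <- rt_t
  }
  class(out) <- "group_stats"
  out
}

# ---- orchestration ---------------------------------------------------------

#' Run the full study pipeline
#'
#' Executes simulate -> preprocess -> specparam -> stats -> cluster -> report
#' on a synthetic cohort defined by the study configuration. All artifacts
#' (config, trial tables, band-averaged spectra, statistics tables, report,
#' manifest) are written under a new run directory that is never overwritten.
#'
#' @param scfg A [study_config()].
#' @param out_dir Parent directory for the run (created if needed).
#' @param run_id Run directory name; defaults to a timestamped name.
#' @param ears,evoked,rt_split Passed to [analyze_subject()].
#' @param cluster If `TRUE`, simulate the source-power grid and run the
#'   condition and correlation cluster tests.
#' @param assemble_recording Passed to [simulate_subject()]; `FALSE` skips
#'   continuous-recording assembly for faster cohort sweeps.
#' @return A list of class `"run_manifest"` (invisibly contains the report).
#' @export
run_study <- function(scfg = study_config(), out_dir = tempfile("cochleamod_"),
                      run_id = NULL, ears = c("left", "right"),
                      evoked = TRUE, rt_split = TRUE, cluster = TRUE,
                      assemble_recording = FALSE) {
  validate_study_config(scfg)
  gen <- scfg$generator
  if (gen$n_subjects < 1) stop("cohort must contain at least one subject")
  if (is.null(run_id)) {
    run_id <- format(Sys.time(), "run_%Y%m%d_%H%M%S")
    k <- 0L
    while (dir.exists(file.path(out_dir, run_id))) {
      k <- k + 1L
      run_id <- sprintf("%s_%d", format(Sys.time(), "run_%Y%m%d_%H%M%S"), k)
    }
  }
  run_dir <- file.path(out_dir, run_id)
  if (dir.exists(run_dir)) stop("run directory already exists: ", run_dir)
  dir.create(run_dir, recursive = TRUE)
  manifest <- list(run_dir = run_dir, package_version =
                     as.character(utils::packageVersion("cochleamod")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    val
  }
  cfg_path <- file.path(run_dir, "config.yaml")
  write_study_config(scfg, cfg_path)

  analyses <- t_stage("simulate_preprocess_specparam", {
    lapply(seq_len(gen$n_subjects), function(i) {
      subj <- simulate_subject(gen, subject_id = i,
                               assemble_recording = assemble_recording,
                               ears = ears)
      utils::write.table(subj$trial_table,
                         file.path(run_dir, sprintf("subject_%02d_trials.tsv", i)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      analyze_subject(subj, scfg, ears = ears, evoked = evoked,
                      rt_split = rt_split)
    })
  })
  spectra_path <- file.path(run_dir, "band_averaged_spectra.tsv")
  write_band_spectra(analyses, spectra_path)
  rej <- do.call(rbind, lapply(analyses, function(a) {
    do.call(rbind, lapply(names(a$ears), function(e) {
      r <- a$ears[[e]]$rejected
      if (nrow(r) == 0) return(NULL)
      cbind(subject = a$subject_id, ear = e, r)
    }))
  }))
  if (is.null(rej)) {
    rej <- data.frame(subject = integer(0), ear = character(0),
                      trial = integer(0), reason = character(0))
  }
  utils::write.table(rej, file.path(run_dir, "rejections.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  stats <- t_stage("stats", cohort_group_stats(analyses, scfg))

  cluster_res <- NULL
  if (cluster) {
    cluster_res <- t_stage("cluster", {
      ami_ref_ear <- if ("right" %in% ears) "right" else ears[1]
      ooa_ami <- vapply(analyses, function(a) {
        a$ears[[ami_ref_ear]]$induced$pooled_ami
      }, numeric(1))
      grid <- simulate_brain_power(gen, ooa_ami,
                                   seed = derive_seed(scfg$seed, 77L))
      fr <- grid$freqs >= scfg$cluster_freq_range[1] &
        grid$freqs <= scfg$cluster_freq_range[2]
      adj <- lattice_adjacency(gen$grid_shape, sum(fr))
      brain_ami <- (grid$power[, , fr, 1] - grid$power[, , fr, 2]) /
        (grid$power[, , fr, 1] + grid$power[, , fr, 2]) * 100
      list(
        condition = condition_cluster_test(
          grid$power[, , fr, , drop = FALSE], adj, n_perm = scfg$n_perm,
          forming_alpha = scfg$forming_alpha,
          seed = derive_seed(scfg$seed, 78L), freqs = grid$freqs[fr]),
        correlation = correlation_cluster_test(
          brain_ami, ooa_ami, adj, n_perm = scfg$n_perm,
          forming_alpha = scfg$forming_alpha,
          seed = derive_seed(scfg$seed, 79L), freqs = grid$freqs[fr])
      )
    })
  }

  report <- t_stage("report", build_report(stats, cluster_res, scfg))
  report_path <- file.path(run_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  write_stats_table(stats, file.path(run_dir, "group_tests.tsv"))

  files <- list.files(run_dir, full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest_path <- file.path(run_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$report <- report
  manifest$analyses <- analyses
  manifest$stats <- stats
  manifest$cluster <- cluster_res
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

# Machine-readable report of the quantities the study design centers on.
build_report <- function(stats, cluster_res, scfg) {
  rep_ears <- function(mode) {
    lapply(stats[[mode]][stats$ears], function(em) {
      list(
        peak_freq_mean_a = em$a$peak_freq_mean, peak_freq_sd_a = em$a$peak_freq_sd,
        peak_freq_mean_v = em$v$peak_freq_mean, peak_freq_sd_v = em$v$peak_freq_sd,
        slope_mean_a = em$a$slope_mean, slope_sd_a = em$a$slope_sd,
        slope_mean_v = em$v$slope_mean, slope_sd_v = em$v$slope_sd,
        pooled_ami_mean = em$pooled_ami_mean, pooled_ami_se = em$pooled_ami_se,
        ami_t = em$ami_t$statistic, ami_p = em$ami_t$p_value,
        ami_p_fdr = em$ami_t$p_fdr %||% em$ami_t$p_value
      )
    })
  }
  out <- list(n_subjects = stats$n_subjects)
  for (mode in intersect(c("induced", "evoked"), names(stats))) {
    out[[mode]] <- rep_ears(mode)
    dq <- stats[[mode]]$dixon_q
    out[[mode]]$dixon_q <- list(successes = dq$successes, tested = dq$tested,
                                proportion = dq$proportion,
                                binomial_p = if (!is.null(dq$binomial)) {
                                  dq$binomial$p_value
                                } else NA)
    if (!is.null(stats[[mode]]$interaural_t)) {
      out[[mode]]$interaural_t <- stats[[mode]]$interaural_t$statistic
      out[[mode]]$interaural_p <- stats[[mode]]$interaural_t$p_value
    }
  }
  if (!is.null(stats$rt_anova_peak)) {
    out$rt_anova <- list(peak = stats$rt_anova_peak,
                         slope = stats$rt_anova_slope,
                         ami = stats$rt_anova_ami)
  }
  if (!is.null(cluster_res)) {
    cl_sum <- function(cr) {
      if (length(cr$clusters) == 0) {
        list(n_clusters = 0, min_p = NA, largest_mass = NA)
      } else {
        list(n_clusters = length(cr$clusters),
             min_p = min(vapply(cr$clusters, `[[`, 0, "p_mc")),
             largest_mass = cr$clusters[[1]]$mass,
             largest_sign = cr$clusters[[1]]$sign,
             largest_p = cr$clusters[[1]]$p_mc,
             largest_size = length(cr$clusters[[1]]$cells))
      }
    }
    out$cluster <- list(condition = cl_sum(cluster_res$condition),
                        correlation = cl_sum(cluster_res$correlation))
  }
  out
}

#' Load the report of a completed run
#'
#' Reads the report and manifest back from a run directory; missing stage
#' outputs are reported as explicit `"stage absent"` entries rather than
#' errors.
#'
#' @param run_dir Run directory created by [run_study()].
#' @return List with `report`, `manifest`, and `missing`.
#' @export
emit_report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("run directory not found: ", run_dir)
  need <- c("report.json", "manifest.json", "config.yaml", "group_tests.tsv")
  present <- file.exists(file.path(run_dir, need))
  missing <- need[!present]
  report <- if ("report.json" %in% missing) "stage absent" else {
    jsonlite::read_json(file.path(run_dir, "report.json"), simplifyVector = TRUE)
  }
  manifest <- if ("manifest.json" %in% missing) "stage absent" else {
    jsonlite::read_json(file.path(run_dir, "manifest.json"), simplifyVector = TRUE)
  }
  list(report = report, manifest = manifest, missing = missing)
}

# ---- tabular writers -------------------------------------------------------

# Tidy test table: one row per group-level test.
write_stats_table <- function(stats, path) {
  rows <- list()
  add <- function(name, t) {
    if (is.null(t)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, statistic = t$statistic %||% NA, df = t$df %||% NA,
      p_raw = t$p_value %||% NA, p_fdr = t$p_fdr %||% NA, n = t$n %||% NA,
      stringsAsFactors = FALSE)
  }
  for (mode in intersect(c("induced", "evoked"), names(stats))) {
    for (ear in stats$ears) {
      add(sprintf("%s_ami_%s", mode, ear), stats[[mode]][[ear]]$ami_t)
      ks <- stats[[mode]][[ear]]$a$ks_uniformity
      add(sprintf("%s_ks_uniformity_%s_auditory", mode, ear), ks)
    }
    add(sprintf("%s_interaural", mode), stats[[mode]]$interaural_t)
  }
  if (!is.null(stats$evoked_phase)) {
    add("evoked_phase_ear", stats$evoked_phase$ear)
    add("evoked_phase_modality", stats$evoked_phase$modality)
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Long-format band-averaged spectra for all subjects/ears/conditions.
write_band_spectra <- function(analyses, path) {
  rows <- list()
  for (a in analyses) {
    for (ear in names(a$ears)) {
      for (cc in c("a", "v")) {
        sp <- band_average(a$ears[[ear]]$induced[[paste0("spectrum_", cc)]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = a$subject_id, ear = ear,
          condition = if (cc == "a") "auditory" else "visual",
          freq = sp$freqs, power = sp$power)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a waveform recording container
#'
#' Recordings are stored as an R serialization of the waveform with its
#' sampling metadata (sampling rate, full scale) — a self-describing
#' container for the package's arbitrary-unit microphone signals.
#'
#' @param recording Numeric waveform with `sampling_rate` (and optionally
#'   `full_scale`) attributes.
#' @param path File path (conventionally `.rds`).
#' @return The path (write) or the recording (read).
#' @export
write_recording <- function(recording, path) {
  stopifnot(!is.null(attr(recording, "sampling_rate")))
  saveRDS(list(waveform = as.numeric(recording),
               sampling_rate = attr(recording, "sampling_rate"),
               full_scale = attr(recording, "full_scale")), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  x <- readRDS(path)
  rec <- x$waveform
  attr(rec, "sampling_rate") <- x$sampling_rate
  attr(rec, "full_scale") <- x$full_scale
  rec
}

#' Read / write trial tables as TSV
#' @param trial_table Data frame.
#' @param path File path.
#' @return The path (write) or the table (read).
#' @export
write_trial_table <- function(trial_table, path) {
  utils::write.table(trial_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a modulation spectrum as TSV + JSON sidecar
#'
#' The power matrix goes to a TSV (rows = carrier bands) and the axes and
#' metadata to a JSON sidecar next to it.
#'
#' @param spec A `"modulation_spectrum"`.
#' @param path TSV path; the sidecar gets the extension `.json`.
#' @return The path, invisibly.
#' @export
write_modulation_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "modulation_spectrum"))
  utils::write.table(spec$power, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(mode = spec$mode, band_centers = spec$band_centers,
               mod_freqs = spec$mod_freqs, n_trials_used = spec$n_trials_used,
               window = spec$window)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_modulation_spectrum
#' @export
read_modulation_spectrum <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  power <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(power) <- NULL
  out <- list(mode = meta$mode, band_centers = meta$band_centers,
              mod_freqs = meta$mod_freqs, power = power,
              n_trials_used = meta$n_trials_used, window = meta$window)
  class(out) <- "modulation_spectrum"
  out
}
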