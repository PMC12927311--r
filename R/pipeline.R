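#' Study configuration
#'
#' Bundles the stimulus, cohort, analysis and statistics parameters of a
#' full study replica: two groups of simulated subjects analysed with the
#' standard chirp EFR battery.
#'
#' Group response strength is controlled jointly by the von Mises phase
#' concentration `kappa` and the evoked `amplitude`; the defaults encode a
#' male-like group with stronger, more phase-locked responses than the
#' female-like group while both groups share the same IGF distribution.
#' The `"desk"` profile keeps the study's subject counts (42 + 38) but
#' uses 100 trials at 200 Hz so a replica runs in a few minutes; the
#' `"full"` profile uses 200 trials at 1000 Hz.
#'
#' @param profile `"desk"` (default) or `"full"`.
#' @param n_f,n_m Subjects per group (defaults 42 and 38).
#' @param n_trials,sample_rate Override the profile's trial count / rate.
#' @param f_lo,f_hi,step Stimulation grid (default 30--60 Hz, 1 Hz).
#' @param n_cycles Morlet cycles (default 14).
#' @param baseline Baseline window in s (default c(-0.5, 0)).
#' @param window_len Averaging window length in s (default 0.150).
#' @param anchor Window anchor, see [frequency_curve()].
#' @param alpha Corrected significance level (default 0.05).
#' @param kappa_f,kappa_m Group-mean phase concentrations.
#' @param amplitude_f,amplitude_m Group-mean evoked amplitudes (uV).
#' @param igf_mean,igf_sd IGF distribution (shared by both groups);
#'   per-subject IGFs are rounded to the grid and clipped to its interior.
#' @param tuning_bw Gaussian tuning bandwidth in Hz.
#' @param noise_scale,noise_exponent Background-noise parameters.
#' @param subject_sdlog Log-normal between-subject spread of kappa and
#'   amplitude.
#' @param seed Master seed for the whole study.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(profile = c("desk", "full"), n_f = 42, n_m = 38,
                         n_trials = NULL, sample_rate = NULL,
                         f_lo = 30, f_hi = 60, step = 1, n_cycles = 14,
                         baseline = c(-0.5, 0), window_len = 0.150,
                         anchor = "cumsum", alpha = 0.05,
                         kappa_f = 0.9, kappa_m = 1.5,
                         amplitude_f = 1.4, amplitude_m = 1.85,
                         igf_mean = 40, igf_sd = 6, tuning_bw = 6,
                         noise_scale = 3, noise_exponent = 1,
                         subject_sdlog = 0.15, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(n_trials)) n_trials <- if (profile == "desk") 100L else 200L
  if (is.null(sample_rate)) sample_rate <- if (profile == "desk") 200 else 1000
  structure(list(profile = profile, n_f = n_f, n_m = n_m,
                 n_trials = as.integer(n_trials), sample_rate = sample_rate,
                 f_lo = f_lo, f_hi = f_hi, step = step, n_cycles = n_cycles,
                 baseline = baseline, window_len = window_len,
                 anchor = anchor, alpha = alpha,
                 kappa_f = kappa_f, kappa_m = kappa_m,
                 amplitude_f = amplitude_f, amplitude_m = amplitude_m,
                 igf_mean = igf_mean, igf_sd = igf_sd, tuning_bw = tuning_bw,
                 noise_scale = noise_scale, noise_exponent = noise_exponent,
                 subject_sdlog = subject_sdlog, seed = as.integer(seed)),
            class = "study_config")
}

#' Draw the per-subject specs of a study
#'
#' Per-subject IGF, kappa and amplitude are sampled deterministically from
#' the config seed: IGF ~ round(Normal(igf_mean, igf_sd)) clipped to the
#' grid interior (same distribution in both groups); kappa and amplitude
#' are log-normal around the group means.
#'
#' @param config A [study_config()].
#' @return List with elements `F` and `M`, each a list of [subject_spec()].
#' @export
study_subjects <- function(config) {
  grid <- frequency_grid(config$f_lo, config$f_hi, config$step)
  lo <- min(grid) ; hi <- max(grid)
  draw <- function(n, group, kappa, amplitude, seed_off) {
    set.seed((config$seed + seed_off) %% 2147483647)
    igf <- pmin(pmax(round(stats::rnorm(n, config$igf_mean, config$igf_sd)),
                     lo), hi - 2)
    kap <- kappa * exp(stats::rnorm(n, 0, config$subject_sdlog))
    amp <- amplitude * exp(stats::rnorm(n, 0, config$subject_sdlog))
    lapply(seq_len(n), function(i)
      subject_spec(sprintf("%s%02d", group, i), group = group,
                   igf = igf[i], kappa = kap[i], amplitude = amp[i],
                   tuning_bw = config$tuning_bw,
                   noise_exponent = config$noise_exponent,
                   noise_scale = config$noise_scale))
  }
  list(F = draw(config$n_f, "F", config$kappa_f, config$amplitude_f, 101L),
       M = draw(config$n_m, "M", config$kappa_m, config$amplitude_m, 202L))
}

analyze_subject <- function(epochs, timeline, grid, config) {
  meas <- compute_measures(epochs, freqs = grid, n_cycles = config$n_cycles,
                           channels = FC9_CHANNELS,
                           baseline = config$baseline)
  out <- list(subject_id = epochs$subject_id, group = epochs$group)
  for (mm in c("pli", "ersp")) {
    curve <- frequency_curve(meas[[mm]], timeline, roi = roi_fc9(),
                             window_len = config$window_len,
                             anchor = config$anchor)
    ig <- extract_igf(curve)
    li_igf <- laterality_index(meas[[mm]], timeline, at = ig$igf,
                               window_len = config$window_len,
                               anchor = config$anchor)
    li_40 <- laterality_index(meas[[mm]], timeline, at = 40,
                              window_len = config$window_len,
                              anchor = config$anchor)
    out[[paste0(mm, "_curve")]] <- curve
    out[[paste0("igf_", mm)]] <- ig$igf
    out[[paste0(mm, "_at_igf")]] <- ig$value_at_igf
    out[[paste0(mm, "_at_40")]] <- ig$value_at_40
    out[[paste0("li_", mm, "_igf")]] <- li_igf$li
    out[[paste0("li_", mm, "_40")]] <- li_40$li
  }
  out
}

#' Run the full study replica
#'
#' Simulates both cohorts, runs the wavelet decomposition, PLI/ERSP
#' extraction, IGF and laterality analysis per subject, and the complete
#' statistical battery: per-frequency rank-sum comparisons with Bonferroni
#' correction for both measures, within-group IGF(PLI) vs IGF(ERSP)
#' signed-rank tests, between-group IGF rank-sum tests, between-group
#' laterality comparisons at IGF and 40 Hz, and Spearman correlations of
#' the response at IGF vs at 40 Hz per group and measure. Deterministic
#' given the config (seed included).
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress (default FALSE).
#' @return An object of class `"efr_study_report"`; see
#'   [write_report()] for the serialized layout.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- frequency_grid(config$f_lo, config$f_hi, config$step)
  timeline <- chirp_timeline(grid)
  subj <- study_subjects(config)
  channels <- stats::setNames(rep(1, length(FC9_CHANNELS)), FC9_CHANNELS)
  rows <- list(); curves <- list(F = list(), M = list())
  for (gname in c("F", "M")) {
    cs <- cohort_spec(subj[[gname]], timeline,
                      n_trials = config$n_trials,
                      sample_rate = config$sample_rate,
                      channels = channels, seed = config$seed)
    for (sp in subj[[gname]]) {
      say("simulating + analysing subject %s", sp$subject_id)
      ep <- simulate_epochs(sp, cs)
      res <- analyze_subject(ep, timeline, grid, config)
      curves[[gname]][[sp$subject_id]] <-
        list(pli = res$pli_curve, ersp = res$ersp_curve)
      res$pli_curve <- res$ersp_curve <- NULL
      res$igf_true <- sp$igf
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  subjects <- do.call(rbind, rows)

  get_curves <- function(g, mm) lapply(curves[[g]], function(cv) cv[[mm]])
  comparison <- list(
    pli = compare_groups_per_frequency(get_curves("F", "pli"),
                                       get_curves("M", "pli"),
                                       alpha = config$alpha),
    ersp = compare_groups_per_frequency(get_curves("F", "ersp"),
                                        get_curves("M", "ersp"),
                                        alpha = config$alpha))

  sF <- subjects[subjects$group == "F", ]
  sM <- subjects[subjects$group == "M", ]
  igf_tests <- list(
    within_F = signed_rank_test(sF$igf_pli, sF$igf_ersp),
    within_M = signed_rank_test(sM$igf_pli, sM$igf_ersp),
    between_pli = rank_sum_test(sF$igf_pli, sM$igf_pli),
    between_ersp = rank_sum_test(sF$igf_ersp, sM$igf_ersp))
  li_tests <- list()
  for (mm in c("pli", "ersp")) for (at in c("igf", "40")) {
    col <- paste0("li_", mm, "_", at)
    li_tests[[col]] <- rank_sum_test(sF[[col]], sM[[col]])
  }
  spearman <- list()
  for (g in c("F", "M")) for (mm in c("pli", "ersp")) {
    ss <- if (g == "F") sF else sM
    spearman[[paste(g, mm, sep = "_")]] <-
      spearman_cor(ss[[paste0(mm, "_at_igf")]], ss[[paste0(mm, "_at_40")]])
  }
  structure(list(config = config, subjects = subjects, curves = curves,
                 comparison = comparison, igf_tests = igf_tests,
                 li_tests = li_tests, spearman = spearman,
                 seed = config$seed),
            class = "efr_study_report")
}

#' @export
print.efr_study_report <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("EFR study replica: %d F + %d M subjects, %d trials @ %g Hz\n",
              sum(s$group == "F"), sum(s$group == "M"),
              x$config$n_trials, x$config$sample_rate))
  for (mm in c("pli", "ersp")) {
    sig <- x$comparison[[mm]]$significant_freqs
    band <- if (length(sig)) sprintf("%g-%g Hz", min(sig), max(sig))
            else "none"
    cat(sprintf("  %s: significant band %s; IGF between-group p = %.3g\n",
                toupper(mm), band,
                x$igf_tests[[paste0("between_", mm)]]$p_value))
  }
  for (g in c("F", "M"))
    cat(sprintf("  mean IGF_PLI (%s) = %.2f Hz, mean LI_PLI at IGF = %+.3f\n",
                g, mean(s$igf_pli[s$group == g]),
                mean(s$li_pli_igf[s$group == g])))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `subjects.tsv` (per-subject IGF/LI table),
#' `comparison_pli.tsv` / `comparison_ersp.tsv` (per-frequency group
#' comparisons), `group_curves.tsv` (group mean and SE per frequency), and
#' `summary.json` (tests, correlations, config, seed).
#'
#' @param report An `"efr_study_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efr_study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$subjects, "subjects.tsv")
  wt(report$comparison$pli$table, "comparison_pli.tsv")
  wt(report$comparison$ersp$table, "comparison_ersp.tsv")
  gc_rows <- list()
  for (g in names(report$curves)) for (mm in c("pli", "ersp")) {
    V <- do.call(rbind, lapply(report$curves[[g]],
                               function(cv) cv[[mm]]$values))
    gc_rows[[paste(g, mm)]] <- data.frame(
      group = g, measure = toupper(mm),
      frequency_hz = report$curves[[g]][[1]][[mm]]$freqs,
      mean = colMeans(V), se = apply(V, 2, stats::sd) / sqrt(nrow(V)))
  }
  wt(do.call(rbind, gc_rows), "group_curves.tsv")
  tidy_test <- function(tt) tt[c("statistic", "p_value", "n1", "n2", "method")]
  summary <- list(
    igf_tests = lapply(report$igf_tests, tidy_test),
    li_tests = lapply(report$li_tests, tidy_test),
    spearman = report$spearman,
    significant_freqs = lapply(report$comparison, `[[`, "significant_freqs"),
    seed = report$seed,
    config = report$config[setdiff(names(report$config), "")])
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Persist / load epochs as a plain-text container
#'
#' Directory layout: `meta.json` (subject id, group, channels, sampling
#' rate, epoch window, dimensions) and `data.tsv` (one row per trial and
#' channel, full `%.17g` precision), lossless under round-trip.
#'
#' @param epochs An `"efr_epochs"` object.
#' @param dir Container directory (created if needed).
#' @return `dir` invisibly (`write_epochs`); an `"efr_epochs"`
#'   (`read_epochs`).
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "efr_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(subject_id = epochs$subject_id, group = epochs$group,
               sample_rate = epochs$sample_rate, channels = epochs$channels,
               t0 = epochs$times[1], n_trials = d[1], n_channels = d[2],
               n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "data.tsv"), "w")
  on.exit(close(con))
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    writeLines(paste(c(tr, epochs$channels[ch],
                       sprintf("%.17g", epochs$data[tr, ch, ])),
                     collapse = "\t"), con)
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @param dir Container directory written by `write_epochs`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "data.tsv"))
  if (length(lines) != meta$n_trials * meta$n_channels)
    stop("malformed container: row count does not match meta.json")
  data <- array(NA_real_,
                dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tr <- as.integer(parts[1])
    ch <- match(parts[2], meta$channels)
    if (is.na(ch)) stop("unknown channel label in container: ", parts[2])
    data[tr, ch, ] <- as.numeric(parts[-(1:2)])
  }
  dimnames(data) <- list(NULL, meta$channels, NULL)
  times <- meta$t0 + (seq_len(meta$n_samples) - 1) / meta$sample_rate
  structure(list(data = data, times = times, sample_rate = meta$sample_rate,
                 channels = meta$channels, subject_id = meta$subject_id,
                 group = meta$group, spec = NULL),
            class = "efr_epochs")
}
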