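# Study orchestration: preprocess -> spectra -> PAC -> connectivity ->
# group statistics, over animals x weeks.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study configuration
#'
#' Bands, windows and stage parameters for [run_study()].  Defaults
#' follow the analysis windows of the underlying study design: theta
#' sub-bands 4-6 / 6-8 Hz, gamma1 50-80 Hz, coherence and network band
#' 4-70 Hz, PDC bands 30-50 / 50-100 Hz, intrasite PAC window
#' 3.5-12.5 x 32-100 Hz, intersite 3.5-11 x 32-100 Hz.
#'
#' @param roles named list mapping canonical site names (CA1L, CA1R,
#'   ...) to channel labels; defaults to identity.
#' @param bands named list of two-element numeric bands (Hz).
#' @param pdc_bands named list of PDC bands (Hz).
#' @param theta_com_band band for the theta center of mass.
#' @param pac_intra_channels channels for intrasite comodulograms.
#' @param pac_inter_pairs list of `c(phase_channel, amp_channel)` pairs.
#' @param pac_intra_window,pac_inter_window lists with `phase` and `amp`
#'   windows (Hz).
#' @param pac_grid `"full"` (2-12 x 10-200 grid) or `"window"` (only
#'   cells inside the mean-PAC window; much faster).
#' @param pac_curve_channels channels for phase-binned amplitude curves.
#' @param pac_curve_phase,pac_curve_amp `c(center, halfwidth)` bands for
#'   the curve's theta phase and gamma amplitude.
#' @param coherence_pairs `NULL` for all pairs, or list of pairs.
#' @param partial_pairs pairs for partial coherence.
#' @param pdc_pairs list of `c(source, sink)` ordered pairs.
#' @param epoch_len_s,epochs_per_session epoching: length (s) and how
#'   many artifact-free epochs to use (`"all"` or a count).
#' @param amp_thresh,flat_thresh artifact-rejection thresholds (uV).
#' @param notch_f0,notch_bw line-noise filter parameters (Hz).
#' @param nperseg,overlap_frac Welch parameters.
#' @param mvar_max_order MVAR order cap for PDC.
#' @param metrics subset of
#'   `c("spectra", "pac_intra", "pac_inter", "pac_curve", "coherence",
#'      "partial_coherence", "eglob", "pdc")`.
#' @param seed RNG seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param output_dir optional directory for CSV outputs and manifest.
#' @return A `study_config` object.
#' @export
study_config <- function(roles = NULL,
                         bands = list(theta_slow = c(4, 6),
                                      theta_high = c(6, 8),
                                      gamma1 = c(50, 80),
                                      coherence = c(4, 70)),
                         pdc_bands = list(gamma_low = c(30, 50),
                                          gamma_high = c(50, 100)),
                         theta_com_band = c(4, 12),
                         pac_intra_channels = c("CA1L", "CA1R", "FL"),
                         pac_inter_pairs = list(c("CA1L", "CA1R"),
                                                c("CA1R", "CA1L")),
                         pac_intra_window = list(phase = c(3.5, 12.5),
                                                 amp = c(32, 100)),
                         pac_inter_window = list(phase = c(3.5, 11),
                                                 amp = c(32, 100)),
                         pac_grid = c("full", "window"),
                         pac_curve_channels = c("CA1L", "CA1R"),
                         pac_curve_phase = c(7.5, 1.5),
                         pac_curve_amp = c(52, 12),
                         coherence_pairs = NULL,
                         partial_pairs = list(c("CA1L", "CA1R")),
                         pdc_pairs = list(c("CA1R", "CA1L"),
                                          c("CA1L", "CA1R")),
                         epoch_len_s = 8, epochs_per_session = "all",
                         amp_thresh = 1000, flat_thresh = 1,
                         notch_f0 = 50, notch_bw = 2,
                         nperseg = 512, overlap_frac = 0.5,
                         mvar_max_order = 20,
                         metrics = c("spectra", "pac_intra", "pac_inter",
                                     "pac_curve", "coherence",
                                     "partial_coherence", "eglob", "pdc"),
                         seed = 1, output_dir = NULL) {
  structure(list(roles = roles, bands = bands, pdc_bands = pdc_bands,
                 theta_com_band = theta_com_band,
                 pac_intra_channels = pac_intra_channels,
                 pac_inter_pairs = pac_inter_pairs,
                 pac_intra_window = pac_intra_window,
                 pac_inter_window = pac_inter_window,
                 pac_grid = match.arg(pac_grid),
                 pac_curve_channels = pac_curve_channels,
                 pac_curve_phase = pac_curve_phase,
                 pac_curve_amp = pac_curve_amp,
                 coherence_pairs = coherence_pairs,
                 partial_pairs = partial_pairs, pdc_pairs = pdc_pairs,
                 epoch_len_s = epoch_len_s,
                 epochs_per_session = epochs_per_session,
                 amp_thresh = amp_thresh, flat_thresh = flat_thresh,
                 notch_f0 = notch_f0, notch_bw = notch_bw,
                 nperseg = nperseg, overlap_frac = overlap_frac,
                 mvar_max_order = mvar_max_order, metrics = metrics,
                 seed = seed, output_dir = output_dir),
            class = "study_config")
}

resolve_role <- function(cfg, name) cfg$roles[[name]] %||% name

pac_grids <- function(cfg, window) {
  if (cfg$pac_grid == "full")
    return(list(phase = seq(2, 12, by = 2), amp = seq(10, 200, by = 5)))
  ph <- seq(2, 12, by = 2)
  am <- seq(10, 200, by = 5)
  list(phase = ph[ph >= window$phase[1L] & ph <= window$phase[2L]],
       amp = am[am >= window$amp[1L] & am <= window$amp[2L]])
}

# metric accumulator: list of row-lists bound into data frames at the end
acc_new <- function() new.env(parent = emptyenv())
acc_add <- function(acc, table, row) {
  acc[[table]] <- c(acc[[table]] %||% list(), list(row))
  invisible(NULL)
}
acc_collect <- function(acc) {
  out <- lapply(as.list(acc), function(rows)
    do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE)))
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

analyze_session <- function(rec, cfg, acc) {
  meta <- rec$meta
  key <- list(animal = meta$animal %||% "animal", group = meta$group %||% "",
              week = meta$week %||% 1L)
  rec <- notch_filter(rec, cfg$notch_f0, cfg$notch_bw)
  eps <- slice_epochs(rec, cfg$epoch_len_s)
  eps <- select_artifact_free(eps, cfg$amp_thresh, cfg$flat_thresh)
  if (is.numeric(cfg$epochs_per_session) &&
      length(eps$epochs) > cfg$epochs_per_session) {
    keep <- seq_len(cfg$epochs_per_session)
    starts <- attr(eps, "starts")[keep]
    eps <- epoch_set(eps$epochs[keep], eps$fs, eps$channels, eps$epoch_len_s)
    attr(eps, "starts") <- starts
  }
  len <- as.integer(round(cfg$epoch_len_s * rec$fs))
  windows <- lapply(attr(eps, "starts"), function(s) c(s, s + len - 1L))

  if ("spectra" %in% cfg$metrics) {
    ps <- welch_psd(eps, cfg$nperseg, cfg$overlap_frac)
    rel <- relative_power(ps)
    for (ch in rec$channels) {
      j <- match(ch, rec$channels)
      keepf <- rel$freqs >= 1 & rel$freqs < 256
      acc_add(acc, "relative_power",
              c(key, list(channel = ch,
                          freq = I(list(rel$freqs[keepf])),
                          relpower = I(list(rel$relpower[keepf, j])))))
    }
    for (bn in names(cfg$bands)[names(cfg$bands) != "coherence"]) {
      bp <- band_power(rel, cfg$bands[[bn]])
      for (ch in rec$channels)
        acc_add(acc, "band_power",
                c(key, list(channel = ch, band = bn, value = bp[[ch]])))
    }
    com <- theta_center_of_mass(ps, cfg$theta_com_band)
    for (ch in rec$channels)
      acc_add(acc, "theta_com", c(key, list(channel = ch, value = com[[ch]])))
  }

  if ("pac_intra" %in% cfg$metrics) {
    g <- pac_grids(cfg, cfg$pac_intra_window)
    for (ch in vapply(cfg$pac_intra_channels, resolve_role,
                      character(1L), cfg = cfg)) {
      cm <- comodulogram(rec, ch, ch, phase_grid = g$phase,
                         amp_grid = g$amp, windows = windows)
      acc_add(acc, "pac_intra",
              c(key, list(channel = ch,
                          value = mean_pac(cm, cfg$pac_intra_window$phase,
                                           cfg$pac_intra_window$amp))))
      for (i in seq_along(cm$phase_freqs))
        for (j in seq_along(cm$amp_freqs))
          acc_add(acc, "comodulogram",
                  c(key, list(phase_channel = ch, amp_channel = ch,
                              f_phase = cm$phase_freqs[i],
                              f_amp = cm$amp_freqs[j],
                              mi = cm$mi[i, j])))
    }
  }

  if ("pac_inter" %in% cfg$metrics) {
    g <- pac_grids(cfg, cfg$pac_inter_window)
    for (pr in cfg$pac_inter_pairs) {
      pc <- resolve_role(cfg, pr[1L]); ac <- resolve_role(cfg, pr[2L])
      cm <- comodulogram(rec, pc, ac, phase_grid = g$phase,
                         amp_grid = g$amp, windows = windows)
      acc_add(acc, "pac_inter",
              c(key, list(phase_channel = pc, amp_channel = ac,
                          value = mean_pac(cm, cfg$pac_inter_window$phase,
                                           cfg$pac_inter_window$amp))))
    }
  }

  if ("pac_curve" %in% cfg$metrics) {
    for (ch in vapply(cfg$pac_curve_channels, resolve_role,
                      character(1L), cfg = cfg)) {
      x <- get_channel(rec, ch)
      phs <- analytic(x, rec$fs, cfg$pac_curve_phase[1L],
                      cfg$pac_curve_phase[2L])
      ams <- analytic(x, rec$fs, cfg$pac_curve_amp[1L],
                      cfg$pac_curve_amp[2L])
      curve <- phase_amplitude_curve(phs, ams)
      shift <- pac_phase_shift(curve)
      acc_add(acc, "phase_shift",
              c(key, list(channel = ch, angle = shift$angle,
                          resultant = shift$resultant_length,
                          mean_amp = mean(curve$mean_amp, na.rm = TRUE))))
    }
  }

  need_S <- any(c("coherence", "partial_coherence", "eglob") %in% cfg$metrics)
  if (need_S) {
    S <- cross_spectral_matrix(eps, cfg$nperseg, cfg$overlap_frac)
    if ("coherence" %in% cfg$metrics) {
      pairs <- cfg$coherence_pairs %||% {
        nch <- length(rec$channels)
        unlist(lapply(seq_len(nch - 1L), function(i)
          lapply((i + 1L):nch, function(j) rec$channels[c(i, j)])),
          recursive = FALSE)
      }
      for (pr in pairs) {
        cf <- coherence(S, pr[1L], pr[2L])
        acc_add(acc, "coherence",
                c(key, list(a = pr[1L], b = pr[2L],
                            value = band_mean_coherence(cf, cfg$bands$coherence))))
      }
    }
    if ("partial_coherence" %in% cfg$metrics) {
      for (pr in cfg$partial_pairs) {
        a <- resolve_role(cfg, pr[1L]); b <- resolve_role(cfg, pr[2L])
        pcf <- partial_coherence(S, a, b)
        acc_add(acc, "partial_coherence",
                c(key, list(a = a, b = b,
                            value = band_mean_coherence(pcf, cfg$bands$coherence))))
      }
    }
    if ("eglob" %in% cfg$metrics) {
      gcoh <- coherence_graph(S, cfg$bands$coherence)
      acc_add(acc, "eglob", c(key, list(value = global_efficiency(gcoh))))
    }
  }

  if ("pdc" %in% cfg$metrics) {
    m <- fit_mvar(eps, cfg$mvar_max_order)
    d <- extended_pdc(m, freqs = seq(0, min(128, rec$fs / 2), by = 1))
    for (bn in names(cfg$pdc_bands))
      for (pr in cfg$pdc_pairs) {
        src <- resolve_role(cfg, pr[1L]); snk <- resolve_role(cfg, pr[2L])
        acc_add(acc, "pdc",
                c(key, list(source = src, sink = snk, band = bn,
                            value = band_mean_pdc(d, cfg$pdc_bands[[bn]],
                                                  src, snk))))
      }
  }
  invisible(NULL)
}

# group comparison for one metric table: buffer vs k18 per week and key
compare_groups <- function(tables) {
  out <- list()
  specs <- list(
    list(tab = "band_power", keys = c("channel", "band"), circular = FALSE),
    list(tab = "theta_com", keys = "channel", circular = FALSE),
    list(tab = "pac_intra", keys = "channel", circular = FALSE),
    list(tab = "pac_inter", keys = c("phase_channel", "amp_channel"),
         circular = FALSE),
    list(tab = "phase_shift", keys = "channel", circular = TRUE),
    list(tab = "coherence", keys = c("a", "b"), circular = FALSE),
    list(tab = "partial_coherence", keys = c("a", "b"), circular = FALSE),
    list(tab = "eglob", keys = character(0), circular = FALSE),
    list(tab = "pdc", keys = c("source", "sink", "band"), circular = FALSE))
  for (sp in specs) {
    df <- tables[[sp$tab]]
    if (is.null(df) || !all(c("group") %in% names(df))) next
    vcol <- if (sp$circular) "angle" else "value"
    groupscols <- c("week", sp$keys)
    split_keys <- interaction(df[groupscols], drop = TRUE, sep = "|")
    for (lev in levels(split_keys)) {
      sub <- df[split_keys == lev, , drop = FALSE]
      a <- sub[[vcol]][sub$group == "buffer"]
      b <- sub[[vcol]][sub$group == "k18"]
      if (sum(is.finite(a)) < 2L || sum(is.finite(b)) < 2L) next
      cmp <- tryCatch(
        if (sp$circular) watson_williams(a, b, metric = sp$tab)
        else two_sample_t(a, b, metric = sp$tab),
        error = function(e) NULL)
      if (is.null(cmp)) next
      keyvals <- sub[1L, groupscols, drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        metric = sp$tab,
        week = keyvals$week,
        key = paste(unlist(keyvals[sp$keys]), collapse = ">"),
        stat_name = cmp$stat_name, stat = cmp$stat, p = cmp$p,
        mean_buffer = cmp$mean_a, mean_k18 = cmp$mean_b,
        ci_buffer_lo = cmp$ci_a[1L], ci_buffer_hi = cmp$ci_a[2L],
        ci_k18_lo = cmp$ci_b[1L], ci_k18_hi = cmp$ci_b[2L],
        n_buffer = cmp$n_a, n_k18 = cmp$n_b,
        significant = cmp$significant,
        note = cmp$note, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full study pipeline over a cohort
#'
#' Preprocessing (notch, epoching, artifact rejection), relative power
#' spectra and band summaries, intrasite and intersite PAC, coherence,
#' partial coherence, network efficiency and extended PDC are computed
#' per animal and week, then compared between groups per week
#' (two-sample t-test; Watson-Williams for phase shifts).  A per-animal
#' stage failure excludes that animal from the affected metrics only and
#' is recorded in the exclusion log.
#'
#' @param cohort a [gen_cohort()] result, a cohort directory (see
#'   [write_cohort()]), or a [cohort_config()] (generated on the fly).
#' @param cfg a [study_config()].
#' @return A `cohort_result`: `tables` (long-format data frames per
#'   metric), `group_stats`, `exclusions`, `config`.  When
#'   `cfg$output_dir` is set, tables are also written as CSV together
#'   with a JSON run manifest.
#' @export
run_study <- function(cohort, cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  if (inherits(cohort, "cohort_config")) cohort <- gen_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  acc <- acc_new()
  excl <- list()
  for (rec in cohort$recordings) {
    err <- tryCatch({ analyze_session(rec, cfg, acc); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err))
      excl[[length(excl) + 1L]] <- data.frame(
        animal = rec$meta$animal %||% "?", week = rec$meta$week %||% NA,
        reason = err, stringsAsFactors = FALSE)
  }
  tables <- acc_collect(acc)
  res <- structure(list(tables = tables,
                        group_stats = compare_groups(tables),
                        exclusions = if (length(excl)) do.call(rbind, excl)
                                     else NULL,
                        config = cfg),
                   class = "cohort_result")
  if (!is.null(cfg$output_dir)) write_cohort_result(res, cfg$output_dir)
  res
}

write_cohort_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$tables)) {
    df <- res$tables[[nm]]
    listcols <- vapply(df, is.list, logical(1L))
    if (any(listcols)) {   # unnest spectra rows (freq/relpower vectors)
      base <- df[!listcols]
      df <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
        cbind(base[rep(i, length(df$freq[[i]])), , drop = FALSE],
              freq = df$freq[[i]], relpower = df$relpower[[i]])))
    }
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(res$group_stats))
    write.csv(res$group_stats, file.path(dir, "group_stats.csv"),
              row.names = FALSE)
  if (!is.null(res$exclusions))
    write.csv(res$exclusions, file.path(dir, "exclusions.csv"),
              row.names = FALSE)
  cfgfile <- tempfile()
  saveRDS(res$config, cfgfile)
  manifest <- list(package = "netdyn",
                   version = as.character(utils::packageVersion("netdyn")),
                   r_version = R.version.string,
                   config_hash = unname(tools::md5sum(cfgfile)),
                   tables = names(res$tables),
                   n_excluded = if (is.null(res$exclusions)) 0L
                                else nrow(res$exclusions))
  unlink(cfgfile)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n  tables:",
      paste(sprintf("%s[%d]", names(x$tables),
                    vapply(x$tables, nrow, integer(1L))), collapse = ", "),
      "\n")
  if (!is.null(x$group_stats))
    cat(sprintf("  group comparisons: %d (%d significant at 0.05)\n",
                nrow(x$group_stats), sum(x$group_stats$significant)))
  if (!is.null(x$exclusions))
    cat(sprintf("  exclusions: %d\n", nrow(x$exclusions)))
  invisible(x)
}
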