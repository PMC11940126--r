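# End-to-end orchestration of the repeated-scan phantom experiment:
# baseline scan(s), re-scan with fresh noise, condition operator, re-scan,
# then envelope -> peaks -> QUS -> summaries -> paired statistics.

#' Define a repeated-scan experiment
#'
#' An experiment has one or more arms, each an explant condition applied
#' after the baseline scans: `operator = "none"` (e.g. brief PBS),
#' `"decalcify"` (EDTA; `front_shift` um, plus `amplitude_drop` dB and bone
#' scatter when `mode = "full"`), or `"swell"` (long PBS; `swell` um).
#' Per-explant seeds are derived deterministically from the master seed.
#'
#' @param arms Named list of arms. Each arm is a list with `operator` and
#'   its parameters (`front_shift`, `amplitude_drop`, `mode`, `swell`), and
#'   optionally `n` to override `n_explants_per_arm`.
#' @param n_explants_per_arm Default explants per arm.
#' @param n_baseline_scans Baseline scans per explant (>= 1; 2 gives the
#'   re-scan precision estimate).
#' @param seed Master integer seed.
#' @return A `qus_design` list.
#' @export
#' @examples
#' experiment_design(
#'   arms = list(
#'     "EDTA-brief" = list(operator = "decalcify", front_shift = 100),
#'     "PBS-brief"  = list(operator = "none")
#'   ),
#'   n_explants_per_arm = 6, seed = 7
#' )
experiment_design <- function(arms, n_explants_per_arm = 6L,
                              n_baseline_scans = 2L, seed = 1L) {
  if (!is.list(arms) || length(arms) < 1L || is.null(names(arms)) ||
      any(names(arms) == "")) {
    stop_cbi("`arms` must be a non-empty named list.")
  }
  for (nm in names(arms)) {
    op <- arms[[nm]]$operator %||% NA_character_
    if (!op %in% c("none", "decalcify", "swell")) {
      stop_cbi("arm '%s' does not resolve to a phantom operator.", nm)
    }
  }
  if (n_explants_per_arm < 1L) stop_cbi("need at least 1 explant per arm.")
  if (n_baseline_scans < 1L) stop_cbi("need at least 1 baseline scan.")
  structure(
    list(arms = arms, n_explants_per_arm = as.integer(n_explants_per_arm),
         n_baseline_scans = as.integer(n_baseline_scans),
         seed = as.integer(seed)),
    class = "qus_design"
  )
}

#' The default demo design
#'
#' Mirrors a two-baseline, one-post-condition study: six explants with a
#' brief 100 um surface-directed decalcification, three with full
#' decalcification (430 um shift, 6.63 dB CBI drop, bone scatter), and
#' three long-PBS controls (102 um swelling).
#'
#' @param seed Master seed.
#' @return A `qus_design`.
#' @export
demo_design <- function(seed = 1L) {
  experiment_design(
    arms = list(
      "EDTA-brief" = list(operator = "decalcify", front_shift = 100, n = 6L),
      "EDTA-full" = list(operator = "decalcify", front_shift = 430,
                         amplitude_drop = 6.63, mode = "full", n = 3L),
      "PBS-long" = list(operator = "swell", swell = 102, n = 3L)
    ),
    n_baseline_scans = 2L, seed = seed
  )
}

apply_arm <- function(spec, arm) {
  switch(arm$operator,
    none = spec,
    decalcify = apply_decalcification(spec,
                                      front_shift = arm$front_shift %||% 0,
                                      amplitude_drop = arm$amplitude_drop %||% 0,
                                      mode = arm$mode %||% "brief"),
    swell = apply_swelling(spec, arm$swell %||% 0)
  )
}

explant_seed <- function(master, arm_i, expl_i) {
  as.integer(((master %% 100000L) * 7919 + arm_i * 1009 + expl_i * 101) %%
               2147483629)
}

run_stage <- function(stage, explant_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_cbi("stage '%s' failed for explant '%s': %s", stage, explant_id,
             conditionMessage(e))
  })
}

process_scan <- function(vol, label, floor) {
  env <- compute_envelope(vol)
  peaks <- detect_volume_peaks(env, floor = floor)
  qus <- compute_qus(env, peaks)
  list(env = env, peaks = peaks, qus = qus,
       summary = summarize_explant(qus, label))
}

#' Run a full phantom experiment
#'
#' For every explant of every arm: simulate the baseline volume, re-simulate
#' it with fresh noise for each additional baseline scan, apply the arm's
#' operator, and re-simulate. Each volume runs through envelope extraction,
#' peak detection, QC and QUS computation. Per-scan peak and QUS tables,
#' per-scan summaries, en face / transverse images, a statistics report and
#' a hashed manifest are written under `out_dir`.
#'
#' Per-line pairing across scans is by grid position; lines failing QC in
#' either member of a pair are dropped from paired differences.
#'
#' @param design A [experiment_design()].
#' @param out_dir Writable output directory (created if needed).
#' @param phantom_args Named list of overrides passed to [phantom_spec()]
#'   (e.g. a smaller `grid` for quick runs).
#' @param thickness_mean,thickness_sd Cohort cartilage thickness
#'   distribution (mm) from which each explant's thickness is drawn.
#' @param floor QC noise floor, V.
#' @param images Write PNG images per explant (default TRUE).
#' @param verbose Log per-stage progress.
#' @return A `qus_experiment` list: `summaries` (per-scan tibble),
#'   `per_explant` (per-explant paired differences, um and dB),
#'   `stats` (the report also written as JSON), `manifest`, `out_dir`.
#' @export
run_experiment <- function(design, out_dir, phantom_args = list(),
                           thickness_mean = 1.072, thickness_sd = 0.209,
                           floor = 0.05, images = TRUE, verbose = FALSE) {
  stopifnot(inherits(design, "qus_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  note_file <- function(p) files <<- c(files, p)

  summaries <- list()
  per_explant <- list()
  for (arm_i in seq_along(design$arms)) {
    arm_name <- names(design$arms)[arm_i]
    arm <- design$arms[[arm_i]]
    n_e <- arm$n %||% design$n_explants_per_arm
    for (e in seq_len(n_e)) {
      expl_id <- sprintf("%s_explant%02d", arm_name, e)
      s_e <- explant_seed(design$seed, arm_i, e)
      th_e <- withr::with_seed(s_e, {
        max(0.5, rnorm(1, thickness_mean, thickness_sd))
      })
      spec_e <- run_stage("phantom", expl_id, {
        do.call(phantom_spec,
                c(list(cartilage_thickness = th_e, seed = s_e), phantom_args))
      })
      edir <- file.path(out_dir, arm_name, sprintf("explant%02d", e))
      dir.create(edir, recursive = TRUE, showWarnings = FALSE)

      scans <- list()
      for (b in seq_len(design$n_baseline_scans)) {
        lab <- sprintf("baseline_%d", b)
        say("simulating %s / %s", expl_id, lab)
        vol <- run_stage("simulate", expl_id,
                         simulate_volume(spec_e, seed = s_e + 1000L + b))
        scans[[lab]] <- run_stage("qus", expl_id,
                                  process_scan(vol, lab, floor))
      }
      spec_post <- run_stage("operator", expl_id, apply_arm(spec_e, arm))
      vol_post <- run_stage("simulate", expl_id,
                            simulate_volume(spec_post, seed = s_e + 2000L))
      scans[["post"]] <- run_stage("qus", expl_id,
                                   process_scan(vol_post, "post", floor))

      last_base <- sprintf("baseline_%d", design$n_baseline_scans)
      for (lab in names(scans)) {
        sc <- scans[[lab]]
        p_peaks <- file.path(edir, paste0(lab, "_peaks.tsv"))
        export_peaks(sc$peaks, p_peaks); note_file(p_peaks)
        p_qus <- file.path(edir, paste0(lab, "_qus.tsv"))
        readr::write_tsv(sc$qus, p_qus); note_file(p_qus)
        summaries[[length(summaries) + 1L]] <- dplyr::mutate(
          sc$summary, arm = arm_name, explant = e, scan = lab,
          .before = 1L)
      }
      if (images) {
        norm <- normalize_full_thickness(scans[[last_base]]$env)
        ef <- enface_segment(norm, scans[[last_base]]$peaks, layer = "CBI")
        p_img <- file.path(edir, "baseline_cbi_enface.png")
        write_enface_png(ef, p_img); note_file(p_img)
        norm_post <- normalize_full_thickness(scans[["post"]]$env)
        ef_post <- enface_segment(norm_post, scans[["post"]]$peaks,
                                  layer = "CBI")
        p_img2 <- file.path(edir, "post_cbi_enface.png")
        write_enface_png(ef_post, p_img2); note_file(p_img2)
        tr <- transverse_slice(scans[["post"]]$env,
                               iy = floor(spec_e$grid$n_y / 2) + 1L,
                               peaks = scans[["post"]]$peaks)
        p_img3 <- file.path(edir, "post_transverse.png")
        # clamp the dB image to a [-40, 0] display range
        write_enface_png(pmin(pmax((tr$values + 40) / 40, 0), 1), p_img3)
        note_file(p_img3)
      }

      paired_post <- pair_qus_records(scans[[last_base]]$qus,
                                      scans[["post"]]$qus)
      prec_um <- if (design$n_baseline_scans >= 2L) {
        mean(pair_qus_records(scans[["baseline_1"]]$qus,
                              scans[[last_base]]$qus)$d_delta_mm) * 1000
      } else NA_real_
      per_explant[[length(per_explant) + 1L]] <- tibble(
        arm = arm_name, explant = e, n_paired_lines = nrow(paired_post),
        d_delta_um = mean(paired_post$d_delta_mm) * 1000,
        d_cbi_db = mean(paired_post$d_cbi_db),
        d_alpha_db_per_mm = mean(paired_post$d_alpha_db_per_mm, na.rm = TRUE),
        prec_um = prec_um
      )
      say("%s done (%d paired lines)", expl_id, nrow(paired_post))
    }
  }
  summaries <- dplyr::bind_rows(summaries)
  per_explant <- dplyr::bind_rows(per_explant)

  stats_report <- experiment_stats(per_explant, design)
  p_sum <- file.path(out_dir, "summaries.tsv")
  readr::write_tsv(summaries, p_sum); note_file(p_sum)
  p_pe <- file.path(out_dir, "per_explant.tsv")
  readr::write_tsv(per_explant, p_pe); note_file(p_pe)
  p_stats <- file.path(out_dir, "stats_report.json")
  jsonlite::write_json(stats_report, p_stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note_file(p_stats)

  manifest <- tibble(
    path = sub(paste0("^", out_dir, "/?"), "", files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  p_manifest <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, p_manifest)

  structure(
    list(summaries = summaries, per_explant = per_explant,
         stats = stats_report, manifest = manifest, out_dir = out_dir),
    class = "qus_experiment"
  )
}

# One-sample paired t on a vector of per-explant differences.
paired_t_from_diffs <- function(d) {
  paired_t_test(tibble(diff = d, ref = 0), diff, ref)
}

experiment_stats <- function(per_explant, design) {
  arms <- split(per_explant, per_explant$arm)
  arm_stats <- lapply(arms, function(a) {
    out <- list(n = nrow(a),
                mean_d_delta_um = mean(a$d_delta_um),
                sd_d_delta_um = if (nrow(a) > 1) sd(a$d_delta_um) else 0,
                mean_d_cbi_db = mean(a$d_cbi_db))
    if (nrow(a) >= 2L && sd(a$d_delta_um) > 0) {
      tt <- paired_t_from_diffs(a$d_delta_um)
      out$t <- tt$statistic; out$df <- tt$df; out$p <- tt$p.value
    }
    out
  })
  prec <- per_explant$prec_um
  precision <- if (all(is.na(prec))) NULL else {
    list(n = sum(!is.na(prec)),
         mean_um = mean(prec, na.rm = TRUE),
         sd_um = if (sum(!is.na(prec)) > 1) sd(prec, na.rm = TRUE) else 0)
  }
  report <- list(seed = design$seed, arms = arm_stats,
                 baseline_precision = precision)
  if (length(arms) >= 2L && all(vapply(arms, nrow, 1L) >= 2L) &&
      all(vapply(arms, function(a) sd(a$d_delta_um) > 0, TRUE))) {
    av <- one_way_anova(per_explant, d_delta_um, arm)
    report$anova_d_delta <- list(F = av$statistic, df_between = av$df_between,
                                 df_within = av$df_within, p = av$p.value)
    none_arm <- names(design$arms)[vapply(design$arms, function(a)
      identical(a$operator, "none"), TRUE)]
    if (length(none_arm) >= 1L) {
      dn <- dunnett_test(per_explant, d_delta_um, arm, control = none_arm[1],
                         n_mc = 20000L, seed = design$seed)
      report$dunnett_d_delta <- list(control = dn$control,
                                     comparison = dn$comparison,
                                     estimate = dn$estimate,
                                     adj_p = dn$p.adjusted, seed = dn$seed)
    }
  }
  report
}

#' Baseline re-scan precision
#'
#' Mean and sd over explants of the paired per-explant difference in Delta
#' between the first and last baseline scans (um). With zero noise the two
#' scans are identical and the precision is exactly (0, 0).
#'
#' @param x A `qus_experiment` from [run_experiment()], its `per_explant`
#'   tibble, or the path of an experiment output directory.
#' @return One-row tibble: `n`, `mean_um`, `sd_um`.
#' @export
baseline_precision <- function(x) {
  pe <- if (inherits(x, "qus_experiment")) x$per_explant
        else if (is.character(x)) {
          readr::read_tsv(file.path(x, "per_explant.tsv"),
                          show_col_types = FALSE)
        } else x
  if (!"prec_um" %in% names(pe) || all(is.na(pe$prec_um))) {
    stop_cbi("no repeat baseline scans: precision requires >= 2 per explant.")
  }
  prec <- pe$prec_um[!is.na(pe$prec_um)]
  tibble(n = length(prec), mean_um = mean(prec),
         sd_um = if (length(prec) > 1) sd(prec) else 0)
}

#' @export
print.qus_experiment <- function(x, ...) {
  cat(sprintf("<qus_experiment> %d scans, %d explants -> %s\n",
              nrow(x$summaries), nrow(x$per_explant), x$out_dir))
  print(dplyr::count(x$per_explant, .data$arm))
  invisible(x)
}
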