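# CSV readers/writers (strict dialect), study configuration, and the
# combined bioequivalence-risk report.

# Strict numeric parse: dot decimal separator only. European decimal
# commas are rejected with the offending line numbers (header is line 1).
parse_numeric_strict <- function(x, column, file) {
  ok <- grepl("^\\s*-?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?\\s*$", x)
  if (!all(ok)) {
    lines <- which(!ok) + 1L
    stop(sprintf("non-numeric value(s) in column `%s` of %s at line(s) %s (strict dialect: dot decimal separator required)",
                 column, file, paste(utils::head(lines, 10), collapse = ", ")))
  }
  as.numeric(x)
}

read_strict_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a calibration-standards CSV
#'
#' Columns `concentration_ug_ml, response`, one row per standard
#' replicate. Strict dialect: dot decimal separator, header required.
#'
#' @param path path to the CSV file.
#' @return Data frame with numeric columns `concentration` (ug/ml) and
#'   `response`, ready for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  df <- read_strict_csv(path, c("concentration_ug_ml", "response"))
  data.frame(
    concentration = parse_numeric_strict(df$concentration_ug_ml,
                                         "concentration_ug_ml", path),
    response = parse_numeric_strict(df$response, "response", path))
}

#' Read a dissolution time-course CSV
#'
#' Columns `formulation_id, replicate_id, detection_mode, time_min,
#' response`. Times in minutes.
#'
#' @param path path to the CSV file.
#' @return Data frame with the same columns, `time_min` and `response`
#'   numeric.
#' @export
read_dissolution_csv <- function(path) {
  df <- read_strict_csv(path, c("formulation_id", "replicate_id",
                                "detection_mode", "time_min", "response"))
  df$time_min <- parse_numeric_strict(df$time_min, "time_min", path)
  df$response <- parse_numeric_strict(df$response, "response", path)
  df
}

#' Read a PAMPA plate CSV
#'
#' Columns `well_id, sample_label, t_h, Ad0, Ar` with incubation time
#' in hours; converted internally to seconds (`t_s`). Duplicate well
#' ids are rejected.
#'
#' @param path path to the CSV file.
#' @return Data frame with columns `well_id`, `sample_label`, `t_s`,
#'   `Ad0`, `Ar`, ready for [pe_timecourse()].
#' @export
read_plate_csv <- function(path) {
  df <- read_strict_csv(path, c("well_id", "sample_label", "t_h", "Ad0", "Ar"))
  dup <- unique(df$well_id[duplicated(df$well_id)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate well_id(s): %s", path,
                 paste(utils::head(dup, 10), collapse = ", ")))
  }
  data.frame(well_id = df$well_id, sample_label = df$sample_label,
             t_s = parse_numeric_strict(df$t_h, "t_h", path) * 3600,
             Ad0 = parse_numeric_strict(df$Ad0, "Ad0", path),
             Ar = parse_numeric_strict(df$Ar, "Ar", path),
             stringsAsFactors = FALSE)
}

#' Write a PAMPA plate CSV
#'
#' Inverse of [read_plate_csv()]: writes `t_s` back out as hours.
#' @param wells data frame with `well_id`, `sample_label`, `t_s`,
#'   `Ad0`, `Ar`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  out <- data.frame(well_id = wells$well_id, sample_label = wells$sample_label,
                    t_h = wells$t_s / 3600, Ad0 = wells$Ad0, Ar = wells$Ar)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dissolution time-course CSV
#'
#' @param profiles data frame with `formulation_id`, `replicate_id`,
#'   `detection_mode`, `time_min` and a response column (`response` or
#'   `pct_released`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(profiles, path) {
  resp <- if ("response" %in% names(profiles)) profiles$response else profiles$pct_released
  out <- data.frame(formulation_id = profiles$formulation_id,
                    replicate_id = profiles$replicate_id,
                    detection_mode = profiles$detection_mode,
                    time_min = profiles$time_min, response = resp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' Bundles the fixed constants and decision thresholds of a combined
#' dissolution + PAMPA study.
#'
#' @param theoretical_max theoretical maximum concentration in the
#'   dissolution vessel, ug/ml; default 1.5 (1.5 mg tablet in 1000 ml).
#' @param f1_max,f2_min similarity thresholds for the f1/f2 verdict;
#'   defaults 15 and 50.
#' @param alpha significance level for group comparisons; default 0.05.
#' @param qc_r2_min minimum r-squared for the reference-panel QC;
#'   default 0.95.
#' @param geometry a [pampa_geometry()].
#' @param scheme a [sampling_scheme()].
#' @param withdrawal_correction apply [correct_cumulative()] to raw
#'   concentrations; default `FALSE`.
#' @param reference formulation id used as the reference profile in
#'   f1/f2 comparisons; `NULL` picks the first (alphabetically last is
#'   never assumed).
#' @param seed optional integer recorded in reports.
#' @return A `study_config` list.
#' @export
study_config <- function(theoretical_max = 1.5, f1_max = 15, f2_min = 50,
                         alpha = 0.05, qc_r2_min = 0.95,
                         geometry = pampa_geometry(),
                         scheme = sampling_scheme(),
                         withdrawal_correction = FALSE,
                         reference = NULL, seed = NULL) {
  if (theoretical_max <= 0) stop("theoretical_max must be positive")
  if (f1_max < 0) stop("f1_max must be >= 0")
  if (f2_min < 0 || f2_min > 100) stop("f2_min must be in [0, 100]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (qc_r2_min <= 0 || qc_r2_min > 1) stop("qc_r2_min must be in (0, 1]")
  structure(list(theoretical_max = theoretical_max, f1_max = f1_max,
                 f2_min = f2_min, alpha = alpha, qc_r2_min = qc_r2_min,
                 geometry = geometry, scheme = scheme,
                 withdrawal_correction = withdrawal_correction,
                 reference = reference, seed = seed),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [study_config()];
#' `geometry` may be a mapping with `Vd`, `Vr`, `S` and `scheme` a
#' mapping with `vessel_volume`, `sample_volume`,
#' `replace_with_medium`. Unknown keys are an error so that typos do
#' not silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("theoretical_max", "f1_max", "f2_min", "alpha", "qc_r2_min",
             "geometry", "scheme", "withdrawal_correction", "reference", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$geometry)) y$geometry <- do.call(pampa_geometry, y$geometry)
  if (!is.null(y$scheme)) y$scheme <- do.call(sampling_scheme, y$scheme)
  do.call(study_config, y)
}

#' Convert raw UV responses to percent released
#'
#' Pipeline helper: inverts responses on a calibration curve, optionally
#' applies the withdrawal correction within each replicate time course,
#' and expresses the result as percent of the theoretical maximum
#' concentration.
#'
#' @param dissolution data frame as from [read_dissolution_csv()] with
#'   a `response` column.
#' @param curve a `calibration_curve` mapping response to ug/ml.
#' @param config a [study_config()]; supplies `theoretical_max`, the
#'   sampling scheme and the correction switch.
#' @return The input with an added numeric `pct_released` column.
#' @export
dissolution_pct_from_responses <- function(dissolution, curve,
                                           config = study_config()) {
  conc <- suppressWarnings(invert_calibration(curve, dissolution$response))
  conc <- as.numeric(conc)
  if (config$withdrawal_correction) {
    key <- interaction(dissolution$formulation_id, dissolution$replicate_id,
                       dissolution$detection_mode, drop = TRUE)
    for (g in split(seq_len(nrow(dissolution)), key)) {
      g <- g[order(dissolution$time_min[g])]
      conc[g] <- correct_cumulative(conc[g], config$scheme)
    }
  }
  dissolution$pct_released <- percent_released_conc(pmax(conc, 0),
                                                    config$theoretical_max)
  dissolution
}

#' Combined bioequivalence-risk report
#'
#' Ties the dissolution and permeability arms together: aggregates
#' replicate dissolution profiles, computes f1/f2 and a similarity
#' verdict per detection mode against the reference formulation,
#' tabulates replicate-aggregated Pe per sample and incubation time,
#' runs Welch comparisons between samples sharing an incubation time,
#' and raises an overall flag when the detection modes disagree on
#' similarity or any Pe comparison is significant -- the two signatures
#' of formulation behavior that dissolution alone can miss.
#'
#' @param dissolution data frame with columns `formulation_id`,
#'   `replicate_id`, `detection_mode`, `time_min`, `pct_released`
#'   (>= 2 formulations). Use [dissolution_pct_from_responses()] to get
#'   `pct_released` from raw responses.
#' @param plates optional data frame of PAMPA wells (`sample_label`,
#'   `t_s`, `Ad0`, `Ar`); `NULL` for a dissolution-only report.
#' @param config a [study_config()].
#' @param plate_map optional named character vector mapping each
#'   `sample_label` to a `formulation_id`; when given, labels must map
#'   to formulations present in `dissolution` and Pe comparisons are
#'   restricted to pairs from different formulations.
#' @return A `be_report` list with elements `version`, `thresholds`,
#'   `dissolution` (profile summaries and per-mode comparisons),
#'   `permeability` (Pe table and pairwise comparisons, or marked
#'   absent) and `flags`.
#' @export
run_be_report <- function(dissolution, plates = NULL,
                          config = study_config(), plate_map = NULL) {
  need <- c("formulation_id", "replicate_id", "detection_mode",
            "time_min", "pct_released")
  if (!all(need %in% names(dissolution))) {
    stop("dissolution must contain columns: ", paste(need, collapse = ", "))
  }
  forms <- unique(dissolution$formulation_id)
  if (length(forms) < 2) stop("need at least 2 formulations in the dissolution data")
  ref <- if (is.null(config$reference)) forms[1] else config$reference
  if (!ref %in% forms) stop("reference formulation not present: ", ref)

  summary_tab <- aggregate_profiles(dissolution)

  # f1/f2 per detection mode, each non-reference formulation vs reference
  comparisons <- list()
  for (mode in unique(summary_tab$detection_mode)) {
    tab <- summary_tab[summary_tab$detection_mode == mode, ]
    ref_tab <- tab[tab$formulation_id == ref, ]
    for (f in setdiff(unique(tab$formulation_id), ref)) {
      test_tab <- tab[tab$formulation_id == f, ]
      shared <- intersect(ref_tab$time_min, test_tab$time_min)
      if (length(shared) < 1) next
      shared <- sort(shared)
      r <- ref_tab$mean_pct[match(shared, ref_tab$time_min)]
      t_ <- test_tab$mean_pct[match(shared, test_tab$time_min)]
      ff <- fit_factors(r, t_, times = shared)
      v <- similarity_verdict(ff, config$f1_max, config$f2_min)
      comparisons[[length(comparisons) + 1]] <- list(
        detection_mode = mode, reference = ref, test = f,
        f1 = ff$f1, f2 = ff$f2, n_points = ff$n_points,
        point_times = ff$point_times, verdict = v$verdict)
    }
  }

  # Permeability arm
  permeability_section <- list(present = FALSE)
  pe_significant <- FALSE
  if (!is.null(plates) && nrow(plates) > 0) {
    if (!is.null(plate_map)) {
      labs <- unique(plates$sample_label)
      unmapped <- setdiff(labs, names(plate_map))
      if (length(unmapped)) {
        stop("plate sample_label(s) missing from plate_map: ",
             paste(unmapped, collapse = ", "))
      }
      unmatched <- setdiff(unname(plate_map[labs]), forms)
      if (length(unmatched)) {
        stop("plate_map maps to formulation(s) absent from dissolution data: ",
             paste(unique(unmatched), collapse = ", "))
      }
    }
    pe_tab <- pe_timecourse(plates, config$geometry)
    pe_comparisons <- list()
    for (tt in unique(plates$t_s)) {
      sub <- plates[plates$t_s == tt, ]
      labs <- unique(sub$sample_label)
      if (length(labs) < 2) next
      pairs <- utils::combn(labs, 2, simplify = FALSE)
      for (pr in pairs) {
        if (!is.null(plate_map) &&
            plate_map[[pr[1]]] == plate_map[[pr[2]]]) next
        pe_a <- pe_per_well(sub[sub$sample_label == pr[1], ], config$geometry)
        pe_b <- pe_per_well(sub[sub$sample_label == pr[2], ], config$geometry)
        if (length(pe_a) < 2 || length(pe_b) < 2) next
        cmp <- compare_groups(pe_a, pe_b, config$alpha)
        pe_significant <- pe_significant || cmp$verdict == "significant"
        pe_comparisons[[length(pe_comparisons) + 1]] <- list(
          t_s = tt, sample_a = pr[1], sample_b = pr[2],
          pe_mean_a = cmp$mean_a, pe_mean_b = cmp$mean_b,
          p_value = cmp$p_value, verdict = cmp$verdict)
      }
    }
    permeability_section <- list(present = TRUE, table = pe_tab,
                                 comparisons = pe_comparisons)
  }

  # Flag when UV and HPLC disagree on similarity for the same pair
  verdicts <- vapply(comparisons, function(x) x$verdict, character(1))
  modes <- vapply(comparisons, function(x) x$detection_mode, character(1))
  tests <- vapply(comparisons, function(x) x$test, character(1))
  verdict_disagreement <- FALSE
  disagreement_detail <- NULL
  for (f in unique(tests)) {
    vs <- unique(verdicts[tests == f])
    if (length(vs) > 1) {
      verdict_disagreement <- TRUE
      disagreement_detail <- c(disagreement_detail, sprintf(
        "formulation %s: %s", f,
        paste(sprintf("%s=%s", modes[tests == f], verdicts[tests == f]),
              collapse = ", ")))
    }
  }

  out <- list(
    version = "1.0",
    seed = config$seed,
    reference = ref,
    thresholds = list(f1_max = config$f1_max, f2_min = config$f2_min,
                      alpha = config$alpha),
    dissolution = list(profiles = summary_tab, comparisons = comparisons),
    permeability = permeability_section,
    flags = list(verdict_disagreement = verdict_disagreement,
                 disagreement_detail = disagreement_detail,
                 pe_significant = pe_significant,
                 overall = verdict_disagreement || pe_significant))
  class(out) <- "be_report"
  out
}

#' Serialize a report to JSON
#'
#' @param report a `be_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "be_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.be_report <- function(x, ...) {
  cat("Bioequivalence-risk report (schema", x$version, ")\n")
  cat("Reference formulation:", x$reference, "\n\n")
  cat("Dissolution similarity (f1 <=", x$thresholds$f1_max,
      ", f2 >=", x$thresholds$f2_min, "):\n")
  for (cmp in x$dissolution$comparisons) {
    cat(sprintf("  [%s] %s vs %s: f1 = %.2f, f2 = %.2f over %d points -> %s\n",
                cmp$detection_mode, cmp$test, cmp$reference,
                cmp$f1, cmp$f2, cmp$n_points, cmp$verdict))
  }
  if (isTRUE(x$permeability$present)) {
    cat("\nPermeability (Pe, x 1e-6 cm/s):\n")
    tab <- x$permeability$table
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s @ %.2f h: Pe = %.2f (RSD %.1f%%, n = %d, excluded %d)\n",
                  tab$sample_label[i], tab$t_s[i] / 3600,
                  tab$pe_mean[i] * 1e6, tab$rsd_pct[i],
                  tab$n_wells[i], tab$n_excluded[i]))
    }
    for (cmp in x$permeability$comparisons) {
      cat(sprintf("  compare %s vs %s @ %.2f h: p = %.4g -> %s\n",
                  cmp$sample_a, cmp$sample_b, cmp$t_s / 3600,
                  cmp$p_value, cmp$verdict))
    }
  } else {
    cat("\nPermeability: absent (no plate data)\n")
  }
  cat("\nFlags: verdict_disagreement =", x$flags$verdict_disagreement,
      "; pe_significant =", x$flags$pe_significant,
      "; OVERALL =", x$flags$overall, "\n")
  if (!is.null(x$flags$disagreement_detail)) {
    for (d in x$flags$disagreement_detail) cat("  ", d, "\n")
  }
  invisible(x)
}
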