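# End-to-end orchestration: simulate/ingest -> filter -> detect ->
# score -> fit, with a structured, versioned report. Identical config
# + seed yields a byte-identical JSON report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline run configuration
#'
#' Exactly one input mode is active: `"simulate"` (synthetic data from
#' a [generator_config()]), `"csv"` (canonical token + participant
#' CSVs) or `"textgrid"` (Praat TextGrid/PitchTier plus a token-design
#' CSV supplying identifiers and flags).
#'
#' @param input_mode `"simulate"`, `"csv"` or `"textgrid"`.
#' @param generator A [generator_config()] (simulate mode).
#' @param tokens_csv,participants_csv Input paths (csv mode).
#' @param textgrid,pitchtier,design_csv Input paths (textgrid mode);
#'   `design_csv` carries `token_id, participant_id, group, item_id,
#'   condition, disfluent, labeling_error` in TextGrid token order.
#' @param tier_config Tier-name mapping for TextGrid import.
#' @param pitch_threshold,length_threshold Detection thresholds
#'   (default 0.10 each).
#' @param models Which mixed models to fit: subset of
#'   `c("glmm", "lmm-duration", "lmm-f0")`.
#' @param lmm_pvalues `"satterthwaite"` or `"wald"`.
#' @param out_dir Output directory for intermediate CSVs and the JSON
#'   report, or `NULL` to write nothing.
#' @param seed Integer seed (simulate mode overrides the generator's).
#' @param include_timestamp Embed a timestamp in the report provenance.
#'   Off by default so identical runs are byte-identical.
#' @return A list of class `pp_run_config`.
#' @export
run_config <- function(input_mode = c("simulate", "csv", "textgrid"),
                       generator = generator_config(),
                       tokens_csv = NULL, participants_csv = NULL,
                       textgrid = NULL, pitchtier = NULL, design_csv = NULL,
                       tier_config = list(syllables = "syllables",
                                          tones = "tones"),
                       pitch_threshold = 0.10, length_threshold = 0.10,
                       models = c("glmm", "lmm-duration", "lmm-f0"),
                       lmm_pvalues = c("satterthwaite", "wald"),
                       out_dir = NULL, seed = NULL,
                       include_timestamp = FALSE) {
  input_mode <- match.arg(input_mode)
  lmm_pvalues <- match.arg(lmm_pvalues)
  models <- if (is.null(models) || length(models) == 0L) character(0)
            else match.arg(models, several.ok = TRUE)
  if (input_mode == "csv" && is.null(tokens_csv)) {
    stop("csv mode requires tokens_csv", call. = FALSE)
  }
  if (input_mode == "textgrid" &&
      (is.null(textgrid) || is.null(pitchtier) || is.null(design_csv))) {
    stop("textgrid mode requires textgrid, pitchtier and design_csv",
         call. = FALSE)
  }
  if (!is.null(seed) && input_mode == "simulate") generator$seed <- as.integer(seed)
  structure(list(input_mode = input_mode, generator = generator,
                 tokens_csv = tokens_csv, participants_csv = participants_csv,
                 textgrid = textgrid, pitchtier = pitchtier,
                 design_csv = design_csv, tier_config = tier_config,
                 pitch_threshold = pitch_threshold,
                 length_threshold = length_threshold,
                 models = models, lmm_pvalues = lmm_pvalues,
                 out_dir = out_dir, seed = seed,
                 include_timestamp = include_timestamp),
            class = "pp_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest/simulate, disfluency filtering, boundary detection,
#' participant scoring, mixed-model fitting, group t-tests and the
#' phrasing-vs-hinting Spearman correlations, in order, writing all
#' intermediate CSVs and the final JSON report when `out_dir` is set.
#' Any stage error halts the run with a stage-labelled message;
#' partial outputs already written are kept.
#'
#' @param config A [run_config()].
#' @return A list of class `pp_run_report`: `filter_report`,
#'   `phrasing_table` (group x condition x label counts and
#'   percentages), `scores`, `fits`, `t_tests`, `correlations`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pp_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dataset <- stage("ingest", switch(
    config$input_mode,
    simulate = generate_dataset(config$generator),
    csv = read_tokens_csv(config$tokens_csv, config$participants_csv),
    textgrid = ingest_textgrid_mode(config)))

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    write_tokens_csv(dataset, file.path(out_dir, "tokens.csv"))
  }

  filtered <- stage("filter", filter_tokens(dataset))
  results <- stage("detect", classify_phrasing(
    filtered$dataset, pitch_threshold = config$pitch_threshold,
    length_threshold = config$length_threshold))
  emit(cbind(filtered$dataset$tokens[
    c("token_id", "participant_id", "group", "item_id", "condition")],
    results[c("pitch_criterion_met", "lengthening_criterion_met",
              "f0_ratio", "dur_ratio", "label")]), "detection.csv")

  scores <- stage("score", score_table(filtered$dataset, results))
  emit(scores, "scores.csv")

  mf <- stage("fit", model_frame(filtered$dataset, results))
  fits <- list()
  if ("glmm" %in% config$models) {
    fits$glmm <- stage("fit", fit_mixed_logit(mf))
    for (g in intersect(GROUP_LEVELS, unique(as.character(mf$group)))) {
      fits[[paste0("glmm_", g)]] <- stage(
        "fit", fit_mixed_logit(mf[mf$group == g, ], group_term = FALSE))
    }
  }
  if ("lmm-duration" %in% config$models) {
    fits$lmm_duration <- stage("fit", fit_lmm_log(
      mf, "duration", pvalues = config$lmm_pvalues))
  }
  if ("lmm-f0" %in% config$models) {
    fits$lmm_f0 <- stage("fit", fit_lmm_log(
      mf, "f0", pvalues = config$lmm_pvalues))
  }

  t_tests <- stage("ttest", pipeline_t_tests(dataset$participants))
  correlations <- stage("correlate", pipeline_correlations(scores))

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    filter_report = filtered$report,
    phrasing_table = phrasing_table(filtered$dataset, results),
    scores = scores,
    fits = fits,
    t_tests = t_tests,
    correlations = correlations,
    provenance = report_provenance(config, dataset)),
    class = "pp_run_report")
  if (!is.null(out_dir)) {
    writeLines(render_report(report, "json"),
               file.path(out_dir, "report.json"))
    writeLines(render_report(report, "markdown"),
               file.path(out_dir, "report.md"))
  }
  report
}

ingest_textgrid_mode <- function(config) {
  frag <- import_textgrid_tokens(config$textgrid, config$pitchtier,
                                 config$tier_config)
  design <- read.csv(config$design_csv, stringsAsFactors = FALSE)
  needed <- c("token_id", "participant_id", "group", "item_id", "condition",
              "disfluent", "labeling_error")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0L) {
    stop("design CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(design) != nrow(frag)) {
    stop("design CSV has ", nrow(design), " rows but the TextGrid ",
         "yielded ", nrow(frag), " tokens", call. = FALSE)
  }
  tokens <- cbind(design[needed],
                  frag[c("dur_s1", "dur_s2", "f0_l", "f0_h")])
  for (col in c("disfluent", "labeling_error")) {
    tokens[[col]] <- parse_bool(tokens[[col]], col)
  }
  participants <- if (!is.null(config$participants_csv)) {
    read_participants_csv(config$participants_csv)
  } else {
    first <- !duplicated(tokens$participant_id)
    data.frame(participant_id = tokens$participant_id[first],
               group = tokens$group[first],
               hinting_score = if ("hinting_score" %in% names(design))
                 as.numeric(design$hinting_score[first]) else NA_real_,
               total_time = NA_real_, speaking_turns = NA_real_,
               stringsAsFactors = FALSE)
  }
  pp_dataset(tokens, participants,
             provenance = sprintf("textgrid import: %s + %s",
                                  config$textgrid, config$pitchtier))
}

# group x condition x label counts and percentages over retained tokens
phrasing_table <- function(dataset, results) {
  tk <- dataset$tokens
  lab <- results$label[match(tk$token_id, results$token_id)]
  tab <- as.data.frame(table(
    group = factor(tk$group, GROUP_LEVELS),
    condition = factor(tk$condition, CONDITION_LEVELS),
    label = factor(lab, c("ONE_AP", "TWO_AP"))), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  cell_n <- stats::ave(tab$n, tab$group, tab$condition, FUN = sum)
  tab$pct <- ifelse(cell_n > 0, 100 * tab$n / cell_n, NA_real_)
  tab
}

pipeline_t_tests <- function(participants) {
  out <- list()
  by_group <- split(participants, participants$group)
  if (!all(GROUP_LEVELS %in% names(by_group))) return(out)
  hc <- by_group$HC; sz <- by_group$SZ
  vars <- c(hinting = "hinting_score", total_time = "total_time",
            speaking_turns = "speaking_turns")
  for (nm in names(vars)) {
    v_sz <- sz[[vars[[nm]]]]; v_hc <- hc[[vars[[nm]]]]
    if (sum(!is.na(v_sz)) >= 2 && sum(!is.na(v_hc)) >= 2) {
      # SZ first so negative t means SZ below HC, as for hinting
      tt <- try(t_test_raw(v_sz[!is.na(v_sz)], v_hc[!is.na(v_hc)]),
                silent = TRUE)
      if (!inherits(tt, "try-error")) {
        out[[nm]] <- cbind(data.frame(comparison = "SZ_vs_HC"), tt)
      }
    }
  }
  out
}

pipeline_correlations <- function(scores) {
  out <- list()
  for (g in GROUP_LEVELS) {
    d <- scores[scores$group == g & !is.na(scores$hinting_score), ]
    if (nrow(d) >= 3 && length(unique(d$phrasing_score)) > 1 &&
        length(unique(d$hinting_score)) > 1) {
      out[[paste0("phrasing_vs_hinting_", g)]] <-
        spearman(d$phrasing_score, d$hinting_score)
    }
  }
  out
}

report_provenance <- function(config, dataset) {
  cfg <- unclass(config)
  cfg$generator <- if (config$input_mode == "simulate")
    unclass(config$generator) else NULL
  cfg$out_dir <- NULL
  prov <- list(schema_version = REPORT_SCHEMA_VERSION,
               package_version = as.character(packageVersion("prosocontrast")),
               config = cfg,
               dataset_provenance = dataset$provenance)
  if (isTRUE(config$include_timestamp)) {
    prov$timestamp <- format(Sys.time(), tz = "UTC")
  }
  prov
}

#' Render a pipeline report
#'
#' @param report A `pp_run_report` from [run_pipeline()].
#' @param format `"json"` (machine-readable, round-trippable) or
#'   `"markdown"` (coefficient tables and group x condition phrasing
#'   percentages).
#' @return A character scalar (json) or vector of lines (markdown).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "pp_run_report"))
  if (format == "json") {
    x <- unclass(report)
    x$fits <- lapply(x$fits, function(f) {
      f <- unclass(f)
      f$fit <- NULL                     # drop the merMod object
      f$variance_components <- as.list(f$variance_components)
      f
    })
    return(jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE,
                            digits = NA, null = "null", pretty = TRUE))
  }
  md <- c("# Prosodic phrasing pipeline report", "")
  fr <- report$filter_report
  md <- c(md, "## Token filtering",
          sprintf("- input: %d; retained: %d (%.2f%%); disfluent: %d; labelling errors: %d",
                  fr$n_input, fr$n_retained, fr$retained_pct,
                  fr$n_removed_disfluent, fr$n_removed_error), "")
  md <- c(md, "## Phrasing by group and condition",
          "| group | condition | label | n | % |",
          "|---|---|---|---|---|")
  pt <- report$phrasing_table
  for (k in seq_len(nrow(pt))) {
    md <- c(md, sprintf("| %s | %s | %s | %d | %.1f |", pt$group[k],
                        pt$condition[k], pt$label[k], pt$n[k], pt$pct[k]))
  }
  md <- c(md, "")
  if (length(report$fits) == 0L) {
    md <- c(md, "## Model fits", "", "_No models were fitted._", "")
  }
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    stat_lab <- if (f$kind == "glmm-logit") "z" else "t"
    md <- c(md, sprintf("## Model: %s (%s)", nm, f$kind),
            sprintf("- formula: `%s`", f$formula),
            sprintf("- n = %d, logLik = %.2f, AIC = %.1f, converged = %s",
                    f$n_obs, f$log_likelihood, f$aic, f$converged), "",
            "**Random effects (intercept variances)**", "",
            "| grouping | variance | sd |", "|---|---|---|")
    for (g in names(f$variance_components)) {
      md <- c(md, sprintf("| %s | %.5f | %.5f |", g,
                          f$variance_components[[g]],
                          sqrt(f$variance_components[[g]])))
    }
    md <- c(md, "", "**Fixed effects**", "",
            sprintf("| term | estimate | SE | %s | p |", stat_lab),
            "|---|---|---|---|---|")
    fe <- f$fixed_effects
    for (k in seq_len(nrow(fe))) {
      md <- c(md, sprintf("| %s | %.4f | %.4f | %.3f | %s |", fe$name[k],
                          fe$estimate[k], fe$std_error[k], fe$statistic[k],
                          format.pval(fe$p_value[k], digits = 3)))
    }
    md <- c(md, "")
  }
  if (length(report$t_tests)) {
    md <- c(md, "## Group comparisons (pooled t)", "",
            "| measure | t | df | p | mean SZ | mean HC |",
            "|---|---|---|---|---|---|")
    for (nm in names(report$t_tests)) {
      tt <- report$t_tests[[nm]]
      md <- c(md, sprintf("| %s | %.2f | %g | %s | %.2f | %.2f |", nm,
                          tt$t, tt$df, format.pval(tt$p_value, digits = 3),
                          tt$mean_1, tt$mean_2))
    }
    md <- c(md, "")
  }
  if (length(report$correlations)) {
    md <- c(md, "## Spearman correlations", "",
            "| pair | rho | n | p |", "|---|---|---|---|")
    for (nm in names(report$correlations)) {
      cr <- report$correlations[[nm]]
      md <- c(md, sprintf("| %s | %.3f | %d | %s |", nm, cr$rho, cr$n,
                          format.pval(cr$p_value, digits = 3)))
    }
    md <- c(md, "")
  }
  md
}

#' Parse a JSON pipeline report back into a report object
#'
#' Inverse of the JSON rendering (modulo the dropped fitted-model
#' objects), so persisted reports can be compared and re-rendered.
#'
#' @param json Character scalar of JSON, or a path to a report file.
#' @return A `pp_run_report`.
#' @export
parse_report_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$filter_report <- as.data.frame(x$filter_report)
  x$phrasing_table <- as.data.frame(x$phrasing_table)
  x$scores <- as.data.frame(x$scores)
  x$fits <- lapply(x$fits, function(f) {
    f$fixed_effects <- as.data.frame(f$fixed_effects)
    f$variance_components <- unlist(f$variance_components)
    f
  })
  x$t_tests <- lapply(x$t_tests, as.data.frame)
  x$correlations <- lapply(x$correlations, as.data.frame)
  structure(x, class = "pp_run_report")
}

#' @export
print.pp_run_report <- function(x, ...) {
  cat("<pp_run_report> schema", x$schema_version, "\n")
  fr <- x$filter_report
  cat(sprintf("  tokens: %d -> %d retained (%.2f%%)\n", fr$n_input,
              fr$n_retained, fr$retained_pct))
  cat("  scored participants:", nrow(x$scores), "\n")
  cat("  fits:", if (length(x$fits)) paste(names(x$fits), collapse = ", ")
      else "none", "\n")
  cat("  t-tests:", if (length(x$t_tests))
    paste(names(x$t_tests), collapse = ", ") else "none", "\n")
  cat("  correlations:", if (length(x$correlations))
    paste(names(x$correlations), collapse = ", ") else "none", "\n")
  invisible(x)
}
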