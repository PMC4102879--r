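# Crossed random-effects models, fitted with lme4 (logistic) and
# lmerTest (linear, for Satterthwaite p-values). Treatment coding
# throughout, with reference levels "given" (condition) and "HC"
# (group), so the condition coefficient is the contrastive effect and
# the group coefficient the SZ effect. The binary phrasing outcome is
# coded TWO_AP = 1.

#' Build the per-token modelling frame
#'
#' Joins phrasing classifications to the dataset and returns one row
#' per analyzable token with the variables the mixed models use.
#'
#' @param dataset A [pp_dataset()] (typically post-[filter_tokens()]).
#' @param results A `pp_phrasing` data.frame from [classify_phrasing()].
#' @return A data.frame with `participant_id`, `item_id`, `condition`,
#'   `group` (factors with reference levels given/HC), `outcome`
#'   (1 = TWO_AP), `dur_s2`, `f0_h`.
#' @export
model_frame <- function(dataset, results) {
  validate_dataset(dataset)
  tk <- dataset$tokens
  idx <- match(tk$token_id, results$token_id)
  if (anyNA(idx)) {
    stop("no phrasing result for token(s): ",
         paste(tk$token_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(
    participant_id = factor(tk$participant_id),
    item_id = factor(tk$item_id),
    condition = factor(tk$condition, levels = CONDITION_LEVELS),
    group = factor(tk$group, levels = GROUP_LEVELS),
    outcome = as.integer(results$label[idx] == "TWO_AP"),
    dur_s2 = tk$dur_s2,
    f0_h = tk$f0_h)
}

#' Mixed-effects logistic regression on the phrasing outcome
#'
#' Fits a binomial GLMM with logit link on the binary phrasing outcome
#' (TWO_AP = 1), with fixed effects for discourse condition, group and
#' (optionally) their interaction, and crossed random intercepts for
#' participant and item, estimated by Laplace approximation
#' ([lme4::glmer()]). With single-group data (or `group_term = FALSE`)
#' the group terms are dropped, as in per-group follow-up fits.
#'
#' @param data A modelling frame from [model_frame()], or any
#'   data.frame with `outcome` (0/1), `condition`, `group`,
#'   `participant_id`, `item_id`.
#' @param include_interaction Include the condition x group
#'   interaction. Default `TRUE`.
#' @param group_term Include group fixed effects; default `NULL`
#'   auto-detects (dropped when only one group level is present).
#' @param random Random-effect structure: `"intercepts"` (the retained
#'   structure) or `"maximal"` (by-participant condition slopes and
#'   by-item condition-by-group slopes, for AIC comparison).
#' @param max_eval Maximum optimizer evaluations (default 20000).
#' @return A `pp_modelfit` list: `formula`, `kind`, `fixed_effects`
#'   (name, estimate, std_error, statistic, p_value), Wald z tests,
#'   `variance_components`, `log_likelihood`, `aic`, `n_obs`,
#'   `n_params`, `converged`, `messages`, and the underlying `fit`.
#' @export
fit_mixed_logit <- function(data, include_interaction = TRUE,
                            group_term = NULL, random = c("intercepts", "maximal"),
                            max_eval = 20000) {
  random <- match.arg(random)
  data <- prepare_model_data(data)
  if (length(unique(data$outcome)) < 2L) {
    stop("outcome is constant; the logistic model is not identifiable ",
         "(complete separation)", call. = FALSE)
  }
  if (is.null(group_term)) group_term <- nlevels(droplevels(data$group)) > 1L
  fixed <- if (!group_term) "condition"
           else if (include_interaction) "condition * group"
           else "condition + group"
  ranef_part <- if (random == "intercepts") {
    "(1 | participant_id) + (1 | item_id)"
  } else if (group_term) {
    "(1 + condition | participant_id) + (1 + condition * group | item_id)"
  } else {
    "(1 + condition | participant_id) + (1 + condition | item_id)"
  }
  fml <- as.formula(paste("outcome ~", fixed, "+", ranef_part))
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = data, family = stats::binomial(),
                control = lme4::glmerControl(
                  optimizer = "bobyqa",
                  optCtrl = list(maxfun = max_eval),
                  calc.derivs = TRUE)),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  as_modelfit(fit, kind = "glmm-logit", data = data, pvalues = "wald")
}

#' Linear mixed model on log-transformed acoustics
#'
#' Fits a linear mixed model on the natural log of an acoustic
#' response -- the duration of the noun's last syllable (`dur_s2`) or
#' its f0 maximum (`f0_h`) -- with the same fixed and random structure
#' as [fit_mixed_logit()]. The log transform normalises within- and
#' across-speaker variability; a multiplicative change of units shifts
#' only the intercept.
#'
#' @inheritParams fit_mixed_logit
#' @param response_kind `"duration"` (log dur_s2) or `"f0"` (log f0_h).
#' @param pvalues `"satterthwaite"` (default; Satterthwaite
#'   denominator df via lmerTest) or `"wald"` (normal approximation).
#'   See [lmm_pb_pvalue()] for a parametric-bootstrap alternative for
#'   a single term.
#' @return A `pp_modelfit` as in [fit_mixed_logit()], with t statistics
#'   per fixed effect.
#' @export
fit_lmm_log <- function(data, response_kind = c("duration", "f0"),
                        include_interaction = TRUE, group_term = NULL,
                        random = c("intercepts", "maximal"),
                        pvalues = c("satterthwaite", "wald"),
                        max_eval = 20000) {
  response_kind <- match.arg(response_kind)
  random <- match.arg(random)
  pvalues <- match.arg(pvalues)
  data <- prepare_model_data(data, need_outcome = FALSE)
  resp_col <- if (response_kind == "duration") "dur_s2" else "f0_h"
  if (!resp_col %in% names(data)) {
    stop("data lacks response column ", resp_col, call. = FALSE)
  }
  if (any(data[[resp_col]] <= 0)) {
    stop("responses must be strictly positive for the log transform",
         call. = FALSE)
  }
  data$log_resp <- log(data[[resp_col]])
  if (is.null(group_term)) group_term <- nlevels(droplevels(data$group)) > 1L
  fixed <- if (!group_term) "condition"
           else if (include_interaction) "condition * group"
           else "condition + group"
  ranef_part <- if (random == "intercepts") {
    "(1 | participant_id) + (1 | item_id)"
  } else if (group_term) {
    "(1 + condition | participant_id) + (1 + condition * group | item_id)"
  } else {
    "(1 + condition | participant_id) + (1 + condition | item_id)"
  }
  fml <- as.formula(paste("log_resp ~", fixed, "+", ranef_part))
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(
                     optCtrl = list(maxfun = max_eval))),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  as_modelfit(fit, kind = paste0("lmm-", response_kind), data = data,
              pvalues = pvalues)
}

prepare_model_data <- function(data, need_outcome = TRUE) {
  data <- as.data.frame(data)
  needed <- c("condition", "group", "participant_id", "item_id",
              if (need_outcome) "outcome")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("model data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (need_outcome && !all(data$outcome %in% c(0, 1))) {
    if (all(data$outcome %in% c("ONE_AP", "TWO_AP"))) {
      data$outcome <- as.integer(data$outcome == "TWO_AP")
    } else {
      stop("outcome must be 0/1 or ONE_AP/TWO_AP labels", call. = FALSE)
    }
  }
  data$condition <- factor(as.character(data$condition),
                           levels = CONDITION_LEVELS)
  data$group <- factor(as.character(data$group), levels = GROUP_LEVELS)
  data$participant_id <- factor(data$participant_id)
  data$item_id <- factor(data$item_id)
  if (nlevels(droplevels(data$participant_id)) < 2L ||
      nlevels(droplevels(data$item_id)) < 2L) {
    stop("need at least 2 participants and 2 items", call. = FALSE)
  }
  data
}

as_modelfit <- function(fit, kind, data, pvalues) {
  smr <- suppressMessages(summary(fit))
  co <- smr$coefficients
  is_glmm <- kind == "glmm-logit"
  if (is_glmm) {
    fe <- data.frame(name = rownames(co), estimate = co[, "Estimate"],
                     std_error = co[, "Std. Error"],
                     statistic = co[, "z value"],
                     p_value = co[, "Pr(>|z|)"],
                     row.names = NULL, stringsAsFactors = FALSE)
  } else if (pvalues == "satterthwaite" && "Pr(>|t|)" %in% colnames(co)) {
    fe <- data.frame(name = rownames(co), estimate = co[, "Estimate"],
                     std_error = co[, "Std. Error"],
                     statistic = co[, "t value"], df = co[, "df"],
                     p_value = co[, "Pr(>|t|)"],
                     row.names = NULL, stringsAsFactors = FALSE)
  } else {
    tval <- co[, "Estimate"] / co[, "Std. Error"]
    fe <- data.frame(name = rownames(co), estimate = co[, "Estimate"],
                     std_error = co[, "Std. Error"], statistic = tval,
                     p_value = 2 * pnorm(-abs(tval)),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc_int <- vc[is.na(vc$var2) & vc$var1 == "(Intercept)" &
                 vc$grp %in% c("participant_id", "item_id"), ]
  variance_components <- setNames(vc_int$vcov, vc_int$grp)
  ll <- logLik(fit)
  n_params <- attr(ll, "df")
  conv_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv_ok <- conv_ok && !any(grepl("failed to converge", msgs %||% character()))
  out <- list(
    formula = deparse1(stats::formula(fit)),
    kind = kind,
    fixed_effects = fe,
    variance_components = variance_components,
    log_likelihood = as.numeric(ll),
    aic = -2 * as.numeric(ll) + 2 * n_params,
    n_obs = nrow(stats::model.frame(fit)),
    n_params = n_params,
    converged = conv_ok,
    messages = as.character(msgs %||% character()),
    fit = fit)
  class(out) <- "pp_modelfit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pp_modelfit <- function(x, ...) {
  cat("<pp_modelfit> ", x$kind, "\n", sep = "")
  cat("  ", x$formula, "\n", sep = "")
  cat("  n =", x$n_obs, " logLik =", format(x$log_likelihood, digits = 6),
      " AIC =", format(x$aic, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  cat("  Random effects (intercept variances):\n")
  for (g in names(x$variance_components)) {
    cat(sprintf("    %-15s %.5f\n", g, x$variance_components[[g]]))
  }
  cat("  Fixed effects:\n")
  fe <- x$fixed_effects
  stat_lab <- if (x$kind == "glmm-logit") "z" else "t"
  for (k in seq_len(nrow(fe))) {
    cat(sprintf("    %-28s %9.4f  SE %7.4f  %s = %7.3f  p = %s\n",
                fe$name[k], fe$estimate[k], fe$std_error[k], stat_lab,
                fe$statistic[k], format.pval(fe$p_value[k], digits = 3)))
  }
  invisible(x)
}

#' Parametric-bootstrap p-value for one fixed-effect term
#'
#' Likelihood-ratio comparison of a fitted mixed model against a null
#' model omitting one term, with the reference distribution obtained
#' by simulating response vectors from the null fit and refitting both
#' models. Offered as a small-sample alternative to the Satterthwaite
#' or Wald approximations.
#'
#' @param fit_full,fit_null `pp_modelfit` objects fitted to the same
#'   data, the null omitting the term of interest.
#' @param n_boot Number of simulated datasets (default 200).
#' @param seed Integer seed for the simulation stream.
#' @return A list with `lrt` (observed likelihood-ratio statistic),
#'   `p_value` (bootstrap tail proportion, add-one corrected) and
#'   `n_boot`.
#' @export
lmm_pb_pvalue <- function(fit_full, fit_null, n_boot = 200, seed = 1L) {
  if (fit_full$n_obs != fit_null$n_obs) {
    stop("fits are on different data", call. = FALSE)
  }
  obs <- 2 * (fit_full$log_likelihood - fit_null$log_likelihood)
  set.seed(seed)
  sims <- stats::simulate(fit_null$fit, nsim = n_boot)
  exceed <- 0L
  for (k in seq_len(n_boot)) {
    y <- sims[[k]]
    f1 <- try(suppressWarnings(suppressMessages(
      lme4::refit(fit_full$fit, y))), silent = TRUE)
    f0 <- try(suppressWarnings(suppressMessages(
      lme4::refit(fit_null$fit, y))), silent = TRUE)
    if (inherits(f1, "try-error") || inherits(f0, "try-error")) next
    stat <- 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0)))
    if (stat >= obs) exceed <- exceed + 1L
  }
  list(lrt = obs, p_value = (exceed + 1) / (n_boot + 1), n_boot = n_boot)
}
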