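# Seeded generator for token-level annotations with the hierarchical
# structure the analysis assumes: a 2-group x 2-condition design with
# crossed participant/item random intercepts on the log-odds of
# two-AP phrasing, acoustic realizations that straddle the 10%
# criteria, and hinting scores monotonically linked to each
# participant's phrasing-marking propensity.

#' Generator configuration
#'
#' Builds a validated configuration for [generate_dataset()]. The
#' default true coefficients and variance components are the published
#' crossed random-intercept logistic fit for this design (on the
#' TWO_AP = 1 scale); the default design is 10 participants per group
#' and 20 critical items, condition-balanced 10/10.
#'
#' @param n_participants_per_group Participants per group (HC and SZ).
#' @param n_items Critical noun-adjective items per participant.
#' @param true_coefficients Named numeric: `intercept`,
#'   `condition_effect` (contrastive), `group_effect` (SZ),
#'   `interaction`, on the log-odds-of-TWO_AP scale.
#' @param var_participant,var_item Random-intercept variances.
#' @param base_dur_s1 Median S1 duration, seconds.
#' @param base_f0_l Median early-L f0, Hz.
#' @param dur_sdlog,f0_sdlog Log-scale SDs of the S1-duration and L-f0
#'   lognormals.
#' @param ratio_ranges List of length-2 numeric ranges from which the
#'   S2/S1 duration ratio and H/L f0 ratio are drawn uniformly, per
#'   latent label: `two_ap_dur`, `one_ap_dur`, `two_ap_f0`,
#'   `one_ap_f0`. TWO_AP ranges must lie at or above 1.10 and ONE_AP
#'   ranges strictly below 1.10, so that with `criterion_noise = 0`
#'   the classifier reconstructs the latent labels exactly.
#' @param criterion_noise Probability in \[0, 1) that a token's
#'   acoustics are realized inconsistently with its latent label.
#' @param dropout_prob Probability a token is flagged as disfluent or
#'   mislabelled (default 0.1925, i.e. 80.75% retention).
#' @param hinting_link List `hc_mean`, `sz_mean`, `sd`,
#'   `propensity_weight`: hinting scores are drawn from a normal
#'   centred at the group mean plus `propensity_weight` times the
#'   participant's centred phrasing-match propensity, then rounded and
#'   clamped to \[0, 20\].
#' @param summary_stats Group mean/SD pairs used by
#'   [generate_summary_fixture()] for `hinting`, `total_time`
#'   (seconds) and `speaking_turns`.
#' @param seed Integer seed; all draws come from one stream.
#' @return A validated list of class `pp_generator_config`.
#' @export
generator_config <- function(
    n_participants_per_group = 10L,
    n_items = 20L,
    true_coefficients = c(intercept = -1.2384, condition_effect = 2.5982,
                          group_effect = 0.5948, interaction = -2.0395),
    var_participant = 0.79490,
    var_item = 0.35673,
    base_dur_s1 = 0.15,
    base_f0_l = 120,
    dur_sdlog = 0.15,
    f0_sdlog = 0.10,
    ratio_ranges = list(two_ap_dur = c(1.12, 1.40),
                        one_ap_dur = c(0.90, 1.08),
                        two_ap_f0 = c(1.12, 1.45),
                        one_ap_f0 = c(0.90, 1.08)),
    criterion_noise = 0,
    dropout_prob = 0.1925,
    hinting_link = list(hc_mean = 17.9, sz_mean = 14.9, sd = 1.8,
                        propensity_weight = 10),
    summary_stats = list(
      hinting = list(hc = c(17.9, 1.5), sz = c(14.9, 2.1)),
      total_time = list(hc = c(169.10, 41.01), sz = c(208.8, 63.46)),
      speaking_turns = list(hc = c(30.0, 2.91), sz = c(31.5, 4.6))),
    seed = 1L) {
  cfg <- list(n_participants_per_group = as.integer(n_participants_per_group),
              n_items = as.integer(n_items),
              true_coefficients = true_coefficients,
              var_participant = var_participant, var_item = var_item,
              base_dur_s1 = base_dur_s1, base_f0_l = base_f0_l,
              dur_sdlog = dur_sdlog, f0_sdlog = f0_sdlog,
              ratio_ranges = ratio_ranges,
              criterion_noise = criterion_noise,
              dropout_prob = dropout_prob,
              hinting_link = hinting_link,
              summary_stats = summary_stats,
              seed = as.integer(seed))
  class(cfg) <- "pp_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants_per_group < 1L || cfg$n_items < 1L) {
    stop("design sizes must be positive", call. = FALSE)
  }
  needed <- c("intercept", "condition_effect", "group_effect", "interaction")
  if (!all(needed %in% names(cfg$true_coefficients))) {
    stop("true_coefficients must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$var_participant < 0 || cfg$var_item < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (cfg$base_dur_s1 <= 0 || cfg$base_f0_l <= 0) {
    stop("base acoustic values must be positive", call. = FALSE)
  }
  rr <- cfg$ratio_ranges
  for (nm in c("two_ap_dur", "one_ap_dur", "two_ap_f0", "one_ap_f0")) {
    r <- rr[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || r[1] <= 0) {
      stop("ratio_ranges$", nm, " must be a positive increasing pair",
           call. = FALSE)
    }
  }
  if (rr$two_ap_dur[1] < 1.10 || rr$two_ap_f0[1] < 1.10) {
    stop("TWO_AP ratio ranges must lie at or above 1.10", call. = FALSE)
  }
  if (rr$one_ap_dur[2] >= 1.10 || rr$one_ap_f0[2] >= 1.10) {
    stop("ONE_AP ratio ranges must lie strictly below 1.10", call. = FALSE)
  }
  for (p in c(cfg$criterion_noise, cfg$dropout_prob)) {
    if (p < 0 || p >= 1) stop("probabilities must lie in [0, 1)",
                              call. = FALSE)
  }
  if (cfg$hinting_link$sd < 0) stop("hinting sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic annotated dataset
#'
#' Simulates the full design: participant and item random intercepts
#' are drawn from normals with the configured variances; each
#' participant x item cell gets a latent TWO_AP label with probability
#' `plogis(eta)` where `eta` sums the true coefficients for its
#' condition/group cell and the two random intercepts; acoustics are
#' realized by drawing S1 duration and L f0 from lognormals and
#' multiplying by a ratio drawn uniformly from the (possibly
#' noise-inverted) label's configured range; `dropout_prob` of tokens
#' are flagged disfluent or mislabelled; hinting scores are linked
#' monotonically to each participant's empirical phrasing-match
#' propensity. Condition alternates by item (balanced split). Fully
#' reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A [pp_dataset()]; the latent labels are carried in the
#'   attribute `"latent"` (a data.frame with `token_id`,
#'   `latent_label`) for generator-vs-pipeline consistency checks.
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  npg <- config$n_participants_per_group
  n_items <- config$n_items
  groups <- rep(GROUP_LEVELS, each = npg)
  pid <- sprintf("P%02d", seq_len(2 * npg))
  iid <- sprintf("I%02d", seq_len(n_items))
  cond <- rep_len(CONDITION_LEVELS, n_items)      # alternate by item

  u_p <- rnorm(2 * npg, 0, sqrt(config$var_participant))
  u_i <- rnorm(n_items, 0, sqrt(config$var_item))
  b <- config$true_coefficients

  grid <- expand.grid(p = seq_len(2 * npg), i = seq_len(n_items),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$p, grid$i), ]
  is_sz <- groups[grid$p] == "SZ"
  is_con <- cond[grid$i] == "contrastive"
  eta <- b[["intercept"]] + b[["condition_effect"]] * is_con +
    b[["group_effect"]] * is_sz + b[["interaction"]] * (is_con & is_sz) +
    u_p[grid$p] + u_i[grid$i]
  n <- nrow(grid)
  latent <- rbinom(n, 1, plogis(eta)) == 1          # TRUE = TWO_AP
  flip <- runif(n) < config$criterion_noise
  realized <- xor(latent, flip)

  dur_s1 <- stats::rlnorm(n, log(config$base_dur_s1), config$dur_sdlog)
  f0_l <- stats::rlnorm(n, log(config$base_f0_l), config$f0_sdlog)
  rr <- config$ratio_ranges
  dur_ratio <- ifelse(realized,
                      runif(n, rr$two_ap_dur[1], rr$two_ap_dur[2]),
                      runif(n, rr$one_ap_dur[1], rr$one_ap_dur[2]))
  f0_ratio <- ifelse(realized,
                     runif(n, rr$two_ap_f0[1], rr$two_ap_f0[2]),
                     runif(n, rr$one_ap_f0[1], rr$one_ap_f0[2]))
  dropped <- runif(n) < config$dropout_prob
  drop_kind <- runif(n) < 0.5                       # disfluency vs error

  tokens <- data.frame(
    token_id = sprintf("%s_%s", pid[grid$p], iid[grid$i]),
    participant_id = pid[grid$p],
    group = groups[grid$p],
    item_id = iid[grid$i],
    condition = cond[grid$i],
    dur_s1 = dur_s1,
    dur_s2 = dur_s1 * dur_ratio,
    f0_l = f0_l,
    f0_h = f0_l * f0_ratio,
    disfluent = dropped & drop_kind,
    labeling_error = dropped & !drop_kind,
    stringsAsFactors = FALSE)

  # hinting linked to the participant's realized match propensity
  expected_two <- is_con
  match <- realized == expected_two
  p_match <- tapply(match, grid$p, mean)[as.character(seq_len(2 * npg))]
  hl <- config$hinting_link
  group_mean_prop <- tapply(p_match, groups, mean)
  centred <- p_match - group_mean_prop[groups]
  mu <- ifelse(groups == "HC", hl$hc_mean, hl$sz_mean) +
    hl$propensity_weight * centred
  hint <- pmin(20, pmax(0, round(rnorm(2 * npg, mu, hl$sd))))

  participants <- data.frame(
    participant_id = pid, group = groups, hinting_score = as.numeric(hint),
    total_time = NA_real_, speaking_turns = NA_real_,
    stringsAsFactors = FALSE)

  ds <- pp_dataset(tokens, participants,
                   provenance = c(
                     sprintf("generate_dataset: seed=%d, %d/group x %d items",
                             config$seed, npg, n_items),
                     sprintf("criterion_noise=%g dropout_prob=%g",
                             config$criterion_noise, config$dropout_prob)))
  attr(ds, "latent") <- data.frame(
    token_id = tokens$token_id,
    latent_label = ifelse(latent, "TWO_AP", "ONE_AP"),
    stringsAsFactors = FALSE)
  ds
}

#' Generate participant-level summary metadata only
#'
#' Draws hinting scores, total task time and speaking-turn counts from
#' the configured per-group normals (defaults are the published group
#' means/SDs), for testing the group-comparison stage in isolation.
#'
#' @param config A [generator_config()]; uses `summary_stats`,
#'   `n_participants_per_group` and `seed`.
#' @return A participant metadata data.frame (`participant_id`,
#'   `group`, `hinting_score`, `total_time`, `speaking_turns`).
#' @export
generate_summary_fixture <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  npg <- config$n_participants_per_group
  groups <- rep(GROUP_LEVELS, each = npg)
  ss <- config$summary_stats
  draw <- function(spec) {
    mu <- ifelse(groups == "HC", spec$hc[1], spec$sz[1])
    sd <- ifelse(groups == "HC", spec$hc[2], spec$sz[2])
    rnorm(2 * npg, mu, sd)
  }
  hint <- pmin(20, pmax(0, round(draw(ss$hinting))))
  data.frame(
    participant_id = sprintf("P%02d", seq_len(2 * npg)),
    group = groups,
    hinting_score = as.numeric(hint),
    total_time = pmax(0, draw(ss$total_time)),
    speaking_turns = pmax(0, round(draw(ss$speaking_turns))),
    stringsAsFactors = FALSE)
}

#' @export
print.pp_generator_config <- function(x, ...) {
  cat("<pp_generator_config>\n")
  cat("  design :", x$n_participants_per_group, "participants/group x",
      x$n_items, "items (seed", paste0(x$seed, ")"), "\n")
  cat("  truth  : intercept", x$true_coefficients[["intercept"]],
      "condition", x$true_coefficients[["condition_effect"]],
      "group", x$true_coefficients[["group_effect"]],
      "interaction", x$true_coefficients[["interaction"]], "\n")
  cat("  var    : participant", x$var_participant, "item", x$var_item, "\n")
  cat("  noise  : criterion", x$criterion_noise,
      "dropout", x$dropout_prob, "\n")
  invisible(x)
}
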