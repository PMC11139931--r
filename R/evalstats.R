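# Model-evaluation statistics: the eight indicators used to score each ET0
# model against a baseline (FAC2, MB, MGE, NMB, NMGE, RMSE, Pearson r,
# refined index of agreement), Taylor-diagram statistics, and ranking.

#' @keywords internal
check_pair <- function(model, obs) {
  if (length(model) != length(obs)) stop("series length mismatch")
  if (length(model) < 1L) stop("empty series")
  keep <- is.finite(model) & is.finite(obs)
  list(m = model[keep], o = obs[keep], n = sum(keep))
}

#' Fraction of predictions within a factor of two
#'
#' The fraction of pairs with 0.5 <= M_i / O_i <= 2. Pairs with a zero
#' observation cannot satisfy the ratio and count as outside the factor
#' of two.
#'
#' @param model,obs Paired numeric series (same length).
#' @return Fraction in 0..1.
#' @export
#' @examples
#' fac2(c(1, 2, 9), c(1, 1, 1))
fac2 <- function(model, obs) {
  p <- check_pair(model, obs)
  ratio <- ifelse(p$o > 0, p$m / p$o, Inf)
  mean(ratio >= 0.5 & ratio <= 2.0)
}

#' Mean bias
#'
#' MB = mean(M_i - O_i): positive when the model on average overestimates.
#'
#' @inheritParams fac2
#' @return Same units as the inputs.
#' @export
mean_bias <- function(model, obs) {
  p <- check_pair(model, obs)
  mean(p$m - p$o)
}

#' Mean gross error
#'
#' MGE = mean(|M_i - O_i|): mean error magnitude irrespective of sign.
#'
#' @inheritParams fac2
#' @return Same units as the inputs.
#' @export
mean_gross_error <- function(model, obs) {
  p <- check_pair(model, obs)
  mean(abs(p$m - p$o))
}

#' Normalised mean bias
#'
#' NMB = sum(M_i - O_i) / sum(O_i), i.e. the mean bias relative to the
#' observed mean.
#'
#' @inheritParams fac2
#' @return Dimensionless.
#' @export
normalized_mean_bias <- function(model, obs) {
  p <- check_pair(model, obs)
  if (sum(p$o) == 0) stop("observed series sums to zero")
  sum(p$m - p$o) / sum(p$o)
}

#' Normalised mean gross error
#'
#' NMGE = sum(|M_i - O_i|) / sum(O_i).
#'
#' @inheritParams fac2
#' @return Dimensionless.
#' @export
normalized_mean_gross_error <- function(model, obs) {
  p <- check_pair(model, obs)
  if (sum(p$o) == 0) stop("observed series sums to zero")
  sum(abs(p$m - p$o)) / sum(p$o)
}

#' Root mean square error
#'
#' RMSE = sqrt(mean((M_i - O_i)^2)).
#'
#' @inheritParams fac2
#' @return Same units as the inputs.
#' @export
rmse <- function(model, obs) {
  p <- check_pair(model, obs)
  sqrt(mean((p$m - p$o)^2))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation with the n-1 normalisation:
#' r = 1/(n-1) sum((M_i - Mbar)/s_M * (O_i - Obar)/s_O).
#' Constant series make r undefined and raise an error rather than
#' returning NaN.
#'
#' @inheritParams fac2
#' @return r in -1..1.
#' @export
pearson_r <- function(model, obs) {
  p <- check_pair(model, obs)
  if (p$n < 2L) stop("need at least two pairs for a correlation")
  sm <- stats::sd(p$m); so <- stats::sd(p$o)
  if (sm == 0 || so == 0) stop("correlation undefined for a constant series")
  sum((p$m - mean(p$m)) / sm * (p$o - mean(p$o)) / so) / (p$n - 1)
}

#' Refined (Willmott) index of agreement
#'
#' The bounded [-1, 1] index built from absolute errors scaled by observed
#' deviations from the observed mean. With A = sum|M_i - O_i| and
#' B = c sum|O_i - Obar|:
#' IOA = 1 - A/B when A <= B, otherwise B/A - 1. Values near +1 indicate
#' close agreement; the scaling constant c defaults to the standard 2.
#'
#' @inheritParams fac2
#' @param c Positive scaling constant (default 2).
#' @return IOA in -1..1.
#' @export
#' @examples
#' ioa_refined(c(1, 2, 3), c(1.1, 2.0, 2.9))
ioa_refined <- function(model, obs, c = 2) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  p <- check_pair(model, obs)
  a <- sum(abs(p$m - p$o))
  b <- c * sum(abs(p$o - mean(p$o)))
  if (b == 0) stop("index of agreement undefined for a constant observed series")
  if (a <= b) 1 - a / b else b / a - 1
}

#' Metric card: all eight statistics for one model-baseline pair
#'
#' @inheritParams fac2
#' @param model_id,baseline_id Identifiers recorded on the card.
#' @param ioa_c Scaling constant for [ioa_refined()].
#' @return One-row data frame with columns `model_id`, `baseline_id`,
#'   `fac2`, `mb`, `mge`, `nmb`, `nmge`, `rmse`, `r`, `ioa`, `n`.
#' @export
#' @examples
#' obs <- eto_series(table3_fixture(), "pan_observed")
#' abt <- eto_series(table3_fixture(), "abtew")
#' metric_card(abt, obs, "abtew", "pan_observed")
metric_card <- function(model, obs, model_id = "model",
                        baseline_id = "obs", ioa_c = 2) {
  p <- check_pair(model, obs)
  data.frame(
    model_id = model_id, baseline_id = baseline_id,
    fac2 = fac2(model, obs),
    mb = mean_bias(model, obs),
    mge = mean_gross_error(model, obs),
    nmb = normalized_mean_bias(model, obs),
    nmge = normalized_mean_gross_error(model, obs),
    rmse = rmse(model, obs),
    r = pearson_r(model, obs),
    ioa = ioa_refined(model, obs, c = ioa_c),
    n = p$n)
}

#' Taylor-diagram statistics
#'
#' Population standard deviations of both series, their Pearson
#' correlation, and the centred root-mean-square difference. The three
#' satisfy the law-of-cosines identity
#' crmsd^2 = sigma_obs^2 + sigma_model^2 - 2 sigma_obs sigma_model r,
#' which is what lets them share one polar plot.
#'
#' @inheritParams fac2
#' @return One-row data frame with `sigma_obs`, `sigma_model`, `r`, `crmsd`.
#' @export
taylor_stats <- function(model, obs) {
  p <- check_pair(model, obs)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(
    sigma_obs = psd(p$o),
    sigma_model = psd(p$m),
    r = pearson_r(model, obs),
    crmsd = psd((p$m - mean(p$m)) - (p$o - mean(p$o))))
}

# direction each metric is ranked in: -1 best-high, +1 best-low (on the
# absolute value for the signed bias metrics)
metric_directions <- c(fac2 = -1, mb = +1, mge = +1, nmb = +1, nmge = +1,
                       rmse = +1, r = -1, ioa = -1)

#' Rank models by one evaluation statistic
#'
#' Orders a set of metric cards (all against the same baseline) from best
#' to worst by the chosen key: descending for FAC2, r and IOA, ascending
#' error magnitude for MB, MGE, NMB, NMGE and RMSE (the signed biases are
#' ranked on |value|). Ties break by ascending RMSE, then model id, so the
#' order is total and deterministic.
#'
#' @param cards A data frame of metric cards (rows from [metric_card()]).
#' @param key One of `"fac2"`, `"mb"`, `"mge"`, `"nmb"`, `"nmge"`,
#'   `"rmse"`, `"r"`, `"ioa"`; default `"ioa"`.
#' @return The cards reordered best-first, with a `rank` column prepended.
#' @export
#' @examples
#' cards <- table4_fixture()
#' rank_models(cards[cards$category == "temperature", ])$model_id
rank_models <- function(cards, key = "ioa") {
  key <- match.arg(key, names(metric_directions))
  if (!all(c(key, "rmse", "model_id") %in% names(cards)))
    stop("cards lack required columns")
  if ("baseline_id" %in% names(cards) &&
      length(unique(cards$baseline_id)) > 1L)
    stop("cards mix baselines; rank one baseline at a time")
  v <- cards[[key]]
  if (key %in% c("mb", "nmb")) v <- abs(v)
  ord <- order(metric_directions[[key]] * v, cards$rmse, cards$model_id)
  out <- cards[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
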