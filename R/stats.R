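# Shared statistics: Pearson correlation, 2^-ddCt relative expression,
# loading-normalized western quantification, and the windowed two-way
# comparison of aligned profiles.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return list with `r`, `p` (two-sided) and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt is the difference of
#' mean dCt between the test and control conditions (replicates averaged
#' before differencing), and relative expression is 2^-ddCt.
#'
#' @param samples data.frame with columns `ct_target`, `ct_reference`,
#'   `condition`.
#' @param test,control condition labels.
#' @return list with `ratio` (= 2^-ddCt), `ddct`, and the per-condition mean
#'   `dct`.
#' @export
ddct_ratio <- function(samples, test = "test", control = "control") {
  need <- c("ct_target", "ct_reference", "condition")
  stopifnot(all(need %in% names(samples)))
  if (any(!is.finite(samples$ct_target)) ||
      any(!is.finite(samples$ct_reference)) ||
      any(samples$ct_target <= 0) || any(samples$ct_reference <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  for (cond in c(test, control)) {
    if (!any(samples$condition == cond)) {
      stop(sprintf("condition '%s' missing from samples", cond),
           call. = FALSE)
    }
  }
  dct <- samples$ct_target - samples$ct_reference
  m_test <- mean(dct[samples$condition == test])
  m_ctl <- mean(dct[samples$condition == control])
  ddct <- m_test - m_ctl
  list(ratio = 2^(-ddct), ddct = ddct,
       dct = c(test = m_test, control = m_ctl))
}

#' Loading-normalized western-blot levels
#'
#' Each band is first divided by its loading-control band; within each
#' culture these ratios are then divided by the mean control-condition
#' ratio, and the per-condition normalized levels are finally averaged
#' across cultures.
#'
#' @param measurements data.frame with columns `band_intensity`,
#'   `loading_intensity`, `condition`, `culture`.
#' @param control control condition label (must be present in every
#'   culture).
#' @return list with `levels` (data.frame `condition`, `level`, `sem`, `n`)
#'   and `per_culture` (the within-culture normalized values).
#' @export
normalize_western <- function(measurements, control = "control") {
  need <- c("band_intensity", "loading_intensity", "condition", "culture")
  stopifnot(all(need %in% names(measurements)))
  if (any(measurements$loading_intensity <= 0)) {
    stop("zero or negative loading intensity", call. = FALSE)
  }
  if (any(measurements$band_intensity <= 0)) {
    stop("band intensities must be > 0", call. = FALSE)
  }
  m <- measurements
  m$ratio <- m$band_intensity / m$loading_intensity
  out <- list()
  for (cu in unique(m$culture)) {
    sub <- m[m$culture == cu, , drop = FALSE]
    ctl <- sub$ratio[sub$condition == control]
    if (!length(ctl)) {
      stop(sprintf("culture '%s' lacks the control condition", cu),
           call. = FALSE)
    }
    sub$norm <- sub$ratio / mean(ctl)
    out[[length(out) + 1L]] <- sub
  }
  per <- do.call(rbind, out)
  agg <- stats::aggregate(norm ~ condition, per, mean)
  sdv <- stats::aggregate(norm ~ condition, per, stats::sd)
  nn <- stats::aggregate(norm ~ condition, per, length)
  levels <- data.frame(condition = agg$condition, level = agg$norm,
                       sem = sdv$norm / sqrt(nn$norm), n = nn$norm)
  list(levels = levels, per_culture = per)
}

#' Windowed two-way comparison of aligned profiles
#'
#' Restricts aligned line profiles to a window centered on the reference
#' peak (200 nm wide by default, i.e. positions within +/- 100 nm) and runs
#' a two-way ANOVA of intensity on condition and position with interaction,
#' via `stats::aov`. Optionally adds Holm-adjusted per-position Welch
#' t-tests between two conditions.
#'
#' @param profiles data.frame with columns `condition`, `synapse`,
#'   `position_nm`, `intensity` (aligned positions, 0 at the reference
#'   peak).
#' @param window window width centered on 0, nm.
#' @param posthoc run per-position pairwise tests (two conditions only).
#' @return list with `anova` (data.frame `term`, `df`, `F`, `p`), `window`
#'   and optionally `posthoc`.
#' @export
window_compare <- function(profiles, window = 200, posthoc = FALSE) {
  need <- c("condition", "synapse", "position_nm", "intensity")
  stopifnot(all(need %in% names(profiles)))
  w <- profiles[abs(profiles$position_nm) <= window / 2, , drop = FALSE]
  if (length(unique(w$position_nm)) < 2) {
    stop("window contains fewer than 2 profile positions", call. = FALSE)
  }
  w$condition <- factor(w$condition)
  w$position <- factor(w$position_nm)
  fit <- stats::aov(intensity ~ condition * position, data = w)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  anova <- data.frame(term = terms[keep], df = tab$Df[keep],
                      F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep])
  out <- list(anova = anova, window = window,
              residual_df = tab$Df[!keep])
  if (posthoc) {
    conds <- levels(w$condition)
    if (length(conds) != 2) {
      stop("posthoc tests require exactly two conditions", call. = FALSE)
    }
    ps <- sort(unique(w$position_nm))
    pv <- vapply(ps, function(p0) {
      a <- w$intensity[w$position_nm == p0 & w$condition == conds[1]]
      b <- w$intensity[w$position_nm == p0 & w$condition == conds[2]]
      stats::t.test(a, b)$p.value
    }, numeric(1))
    out$posthoc <- data.frame(position_nm = ps, p = pv,
                              p_adj = stats::p.adjust(pv, "holm"))
  }
  out
}
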