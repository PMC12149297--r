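#' Regional summary of a per-channel metric
#'
#' Arithmetic means of a per-channel metric over the 19-channel montage,
#' the 7 rostral channels and the 7 caudal channels, plus the rostrocaudal
#' asymmetry index (rostral mean minus caudal mean; positive values
#' indicate rostral dominance, negative values caudal dominance).
#'
#' @param values named numeric vector, one value per montage channel.
#' @param montage a [Montage-class] (default [standardMontage()]).
#' @param metric metric name carried into the output.
#' @param subjectId subject identifier carried into the output.
#' @return one-row data.frame: `subject_id`, `metric`, `global_mean`,
#'   `rostral_mean`, `caudal_mean`, `asymmetry`.
#' @export
regionalSummary <- function(values, montage = standardMontage(),
                            metric = NA_character_,
                            subjectId = NA_character_) {
  missing <- setdiff(montageChannels(montage), names(values))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  rost <- mean(values[rostralChannels(montage)])
  caud <- mean(values[caudalChannels(montage)])
  data.frame(subject_id = subjectId, metric = metric,
             global_mean = mean(values[montageChannels(montage)]),
             rostral_mean = rost, caudal_mean = caud,
             asymmetry = rost - caud, row.names = NULL)
}

#' Cohen's d with the pooled standard deviation
#'
#' `(mean1 - mean2) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`. The sign
#' follows the first group minus the second.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @return Cohen's d.
#' @export
cohensD <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(group1) - mean(group2)) / sqrt(sp2)
}

#' One-way ANOVA with r-squared effect size
#'
#' Standard fixed-effects one-way analysis of variance; the effect size is
#' `r^2 = SS_between / SS_total`.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each n >= 2).
#' @return one-row data.frame: `test`, `statistic` (F), `df1`, `df2`, `p`,
#'   `effect` (r^2), `degenerate` (TRUE when all values are identical).
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  if (max(values) - min(values) == 0)
    return(data.frame(test = "one_way_anova", statistic = NA_real_,
                      df1 = nlevels(groups) - 1L,
                      df2 = length(values) - nlevels(groups),
                      p = NA_real_, effect = 0, degenerate = TRUE))
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssb <- tab["groups", "Sum Sq"]
  sst <- sum(tab[, "Sum Sq"])
  data.frame(test = "one_way_anova", statistic = tab["groups", "F value"],
             df1 = tab["groups", "Df"], df2 = tab["Residuals", "Df"],
             p = tab["groups", "Pr(>F)"], effect = ssb / sst,
             degenerate = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-adjusted p-values for every group pair, reported
#' alongside the per-pair pooled two-sample t statistic (df = n1 + n2 - 2)
#' and Cohen's d, the quantities conventionally printed with such
#' comparisons.
#'
#' @inheritParams oneWayAnova
#' @return data.frame, one row per pair: `group1`, `group2`, `t`, `df`,
#'   `d`, `p_tukey`.
#' @export
tukeyHsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- lapply(seq_along(pairs), function(i) {
    g1 <- pairs[[i]][1]; g2 <- pairs[[i]][2]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    n1 <- length(v1); n2 <- length(v2)
    d <- cohensD(v1, v2)
    data.frame(group1 = g1, group2 = g2,
               t = d * sqrt(n1 * n2 / (n1 + n2)),
               df = n1 + n2 - 2L, d = d,
               p_tukey = tk[i, "p adj"], row.names = NULL)
  })
  do.call(rbind, out)
}

#' MANOVA with Pillai's trace
#'
#' One-way multivariate analysis of variance reporting Pillai's trace and
#' its standard F approximation.
#'
#' @param Y numeric matrix, observations x variables (>= 2 variables).
#' @param groups group label per row.
#' @return one-row data.frame: `test`, `statistic` (Pillai's trace), `F`,
#'   `df1`, `df2`, `p`.
#' @export
pillaiManova <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  if (ncol(Y) < 2) stop("MANOVA needs >= 2 response variables")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (nrow(Y) <= ncol(Y) + nlevels(groups))
    stop("too few observations for the number of variables and groups")
  fit <- tryCatch(stats::manova(Y ~ groups),
                  error = function(e) stop("MANOVA failed: ",
                                           conditionMessage(e)))
  st <- tryCatch(summary(fit, test = "Pillai")$stats,
                 error = function(e) stop(
                   "singular within-group covariance: ",
                   conditionMessage(e)))
  data.frame(test = "pillai_manova", statistic = st["groups", "Pillai"],
             F = st["groups", "approx F"],
             df1 = st["groups", "num Df"], df2 = st["groups", "den Df"],
             p = st["groups", "Pr(>F)"], row.names = NULL)
}

#' Mann-Whitney U test
#'
#' Rank-sum test reporting the U statistic under the min convention
#' (`U = min(U1, U2)`), an exact p-value for small tie-free samples and the
#' tie-corrected normal approximation otherwise, plus Cohen's d as the
#' effect size conventionally reported alongside.
#'
#' @param group1,group2 numeric vectors.
#' @return one-row data.frame: `test`, `U`, `p`, `d`.
#' @export
mannWhitneyU <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1 || n2 < 1) stop("empty group")
  r <- rank(c(group1, group2))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  wt <- suppressWarnings(stats::wilcox.test(group1, group2))
  d <- if (n1 >= 2 && n2 >= 2 &&
           (stats::var(group1) > 0 || stats::var(group2) > 0))
    cohensD(group1, group2) else NA_real_
  data.frame(test = "mann_whitney_u", U = U, p = wt$p.value, d = d,
             row.names = NULL)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into the K^2 omnibus statistic (chi-squared, 2 df). Reported as a
#' screening diagnostic; it does not switch tests automatically.
#'
#' @param x numeric vector, n >= 8.
#' @return one-row data.frame: `test`, `K2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostinoPearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
         ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  data.frame(test = "dagostino_pearson", K2 = K2,
             p = stats::pchisq(K2, 2, lower.tail = FALSE),
             z_skew = z1, z_kurt = z2, row.names = NULL)
}

#' Channelwise t map with FDR correction
#'
#' Per-channel pooled two-sample t statistics for one group comparison,
#' with Benjamini-Hochberg adjustment across the channels of the map (one
#' family per metric x comparison) and a significance mask at the given
#' alpha level.
#'
#' @param values numeric matrix, subjects x channels.
#' @param groups group label per row of `values`.
#' @param comparison character(2): the two group labels to compare
#'   (first minus second).
#' @param alphaLevel significance level for the mask (default 0.05).
#' @return data.frame, one row per channel: `channel`, `t`, `df`, `p`,
#'   `p_fdr`, `significant`, `group1`, `group2`.
#' @export
channelwiseTMap <- function(values, groups, comparison, alphaLevel = 0.05) {
  stopifnot(length(comparison) == 2)
  i1 <- groups == comparison[1]; i2 <- groups == comparison[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("each group needs >= 2 subjects")
  res <- lapply(seq_len(ncol(values)), function(j) {
    tt <- stats::t.test(values[i1, j], values[i2, j], var.equal = TRUE)
    data.frame(channel = colnames(values)[j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < alphaLevel
  out$group1 <- comparison[1]; out$group2 <- comparison[2]
  out
}
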