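#' Competitive regression of proximity metrics on transition responses
#'
#' The workhorse of both the neural and the behavioural analyses: for each
#' subject, the n(n-1) per-transition responses are regressed (ordinary
#' least squares, with intercept) on one column per proximity metric, letting
#' the metrics compete for variance; group-level inference is a two-tailed
#' one-sample t-test on each coefficient across subjects.
#'
#' @param cohort a `transition_cohort` data frame (columns `subject`,
#'   `predecessor`, `object`, `response`), e.g. from
#'   [simulate_adaptation_cohort()] or [preprocess_rt()].
#' @param regressors named list of proximity matrices (see
#'   [proximity_regressor()]); values are looked up at each (predecessor,
#'   object) pair.
#' @param center mean-centre each regressor column before fitting (default);
#'   does not change slopes, only the intercept.
#' @param scale divide each regressor column by its standard deviation
#'   (z-scoring when combined with `center`).
#' @return An object of class `transition_regression`: per-subject
#'   coefficient matrix, group summary table (`estimate`, `se`, `t`, `df`,
#'   `p`), and the model descriptor.
#' @examples
#' g <- default_reduced_graph()
#' cfg <- cohort_config(n_subjects = 8, generative_metric = "link",
#'                      beta_metric = 2, noise_sd = 0.5, seed = 42)
#' coh <- simulate_adaptation_cohort(cfg, g)
#' fit <- transition_regression(coh, list(link = link_distance_matrix(g)))
#' coef(fit)
#' @export
transition_regression <- function(cohort, regressors, center = TRUE,
                                  scale = FALSE) {
  stopifnot(is.data.frame(cohort),
            all(c("subject", "predecessor", "object", "response") %in%
                  names(cohort)))
  if (!is.list(regressors) || is.null(names(regressors)) ||
      any(!nzchar(names(regressors)))) {
    stop("'regressors' must be a named list of proximity matrices")
  }
  subjects <- unique(cohort$subject)
  x_all <- vapply(regressors, function(m) {
    m <- as.matrix(m)
    m[cbind(as.character(cohort$predecessor),
            as.character(cohort$object))]
  }, numeric(nrow(cohort)))
  coefs <- matrix(NA_real_, length(subjects), length(regressors),
                  dimnames = list(subjects, names(regressors)))
  for (k in seq_along(subjects)) {
    rows <- cohort$subject == subjects[k]
    x <- x_all[rows, , drop = FALSE]
    x <- base::scale(x, center = center, scale = scale)
    design <- cbind(`(intercept)` = 1, x)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
      stop("design is rank deficient for subject ", subjects[k],
           "; collinear regressor(s): ", paste(dropped, collapse = ", "))
    }
    fit <- stats::lm.fit(design, cohort$response[rows])
    coefs[k, ] <- fit$coefficients[names(regressors)]
  }
  group <- group_ttests(coefs)
  structure(list(coefficients = coefs, group = group,
                 n_subjects = length(subjects),
                 regressors = names(regressors),
                 center = center, scale = scale),
            class = "transition_regression")
}

## One-sample two-tailed t-test per column; zero across-subject variance is
## flagged (NA statistics + warning) rather than an error.
group_ttests <- function(coefs) {
  n <- nrow(coefs)
  est <- colMeans(coefs)
  se <- apply(coefs, 2L, stats::sd) / sqrt(n)
  t_stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, NA_real_))
  degenerate <- se == 0 & est != 0
  if (any(degenerate)) {
    warning("zero across-subject variance for regressor(s): ",
            paste(names(est)[degenerate], collapse = ", "),
            "; group t undefined")
  }
  p <- ifelse(is.na(t_stat), NA_real_,
              2 * stats::pt(-abs(t_stat), df = n - 1L))
  data.frame(regressor = colnames(coefs), estimate = est, se = se,
             t = t_stat, df = n - 1L, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.transition_regression <- function(x, digits = 4L, ...) {
  cat("Competitive transition regression (", x$n_subjects, " subjects; ",
      "per-subject OLS + group one-sample t)\n", sep = "")
  print(format(x$group, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.transition_regression <- function(object, ...) {
  object
}

#' @export
coef.transition_regression <- function(object, ...) {
  stats::setNames(object$group$estimate, object$group$regressor)
}

#' Distance contrasts and repeated-measures ANOVA
#'
#' The model-free analysis of distance-dependent adaptation: per subject,
#' responses are binned by link distance (1, 2, 3); the contrasts are (i)
#' connected (distance 1) versus non-connected (distances 2-3 pooled) and
#' (ii) distance 2 versus distance 3, both as paired two-tailed t-tests; and
#' a one-way repeated-measures ANOVA over the three distance bins.  Optional
#' per-object demeaning (subtracting each subject's mean response to each
#' object) checks that the effects are not driven by object main effects.
#'
#' @param cohort a `transition_cohort` data frame.
#' @param link link-distance proximity matrix for the underlying graph.
#' @param demean_objects subtract per-subject object means first.
#' @return An object of class `distance_contrasts`: per-subject bin means,
#'   both paired contrasts, and the ANOVA table (`F`, `df1`, `df2`, `p`).
#' @export
distance_contrasts <- function(cohort, link, demean_objects = FALSE) {
  stopifnot(is.data.frame(cohort))
  link <- as.matrix(link)
  d <- link[cbind(as.character(cohort$predecessor),
                  as.character(cohort$object))]
  bins <- sort(unique(round(d)))
  if (!all(bins %in% 1:3)) {
    stop("distance contrasts expect link distances in {1, 2, 3}")
  }
  if (length(bins) < 3L) {
    stop("empty distance bin(s): ", paste(setdiff(1:3, bins), collapse = ", "))
  }
  resp <- cohort$response
  if (demean_objects) {
    key <- interaction(cohort$subject, cohort$object, drop = TRUE)
    resp <- resp - stats::ave(resp, key)
  }
  subjects <- unique(cohort$subject)
  bin_means <- t(vapply(subjects, function(s) {
    rows <- cohort$subject == s
    vapply(1:3, function(b) mean(resp[rows & d == b]), 0)
  }, numeric(3L)))
  dimnames(bin_means) <- list(subjects, paste0("link", 1:3))

  t_conn <- paired_t(bin_means[, 1L], (bin_means[, 2L] + bin_means[, 3L]) / 2)
  t_23 <- paired_t(bin_means[, 2L], bin_means[, 3L])
  aov_res <- rm_anova_oneway(bin_means)
  structure(list(bin_means = bin_means, connected_vs_nonconnected = t_conn,
                 link2_vs_link3 = t_23, anova = aov_res,
                 demean_objects = demean_objects),
            class = "distance_contrasts")
}

## Paired two-tailed t-test, returning t = 0 (p = 1) when all differences
## vanish instead of erroring on zero variance.
paired_t <- function(x, y) {
  diff <- x - y
  n <- length(diff)
  se <- stats::sd(diff) / sqrt(n)
  if (se == 0) {
    return(list(estimate = mean(diff), t = 0, df = n - 1L,
                p = if (mean(diff) == 0) 1 else NA_real_))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(estimate = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

## One-way repeated-measures ANOVA on a subjects x conditions matrix of cell
## means, fitted through stats::aov with a subject error stratum.  A zero
## between-condition sum of squares returns F = 0 by convention (covers the
## degenerate all-equal case, where the error stratum is empty too).
rm_anova_oneway <- function(cell_means) {
  n_s <- nrow(cell_means)
  n_c <- ncol(cell_means)
  long <- data.frame(y = as.vector(cell_means),
                     subject = factor(rep(seq_len(n_s), times = n_c)),
                     cond = factor(rep(seq_len(n_c), each = n_s)))
  ss_cond <- n_s * sum((colMeans(cell_means) - mean(cell_means))^2)
  if (ss_cond < .Machine$double.eps^0.75 * max(1, sum(cell_means^2))) {
    return(list(F = 0, df1 = n_c - 1L, df2 = (n_c - 1L) * (n_s - 1L),
                p = 1))
  }
  fit <- stats::aov(y ~ cond + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  list(F = tab["cond", "F value"], df1 = tab["cond", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["cond", "Pr(>F)"])
}

#' @export
print.distance_contrasts <- function(x, digits = 4L, ...) {
  cat("Distance contrasts over link-distance bins",
      if (x$demean_objects) "(object-demeaned)", "\n")
  cat("  group bin means:",
      paste(sprintf("%s = %.*g", colnames(x$bin_means), digits,
                    colMeans(x$bin_means)), collapse = ", "), "\n")
  with(x$connected_vs_nonconnected,
       cat(sprintf("  connected vs non-connected: t(%d) = %.*g, p = %.*g\n",
                   df, digits, t, digits, p)))
  with(x$link2_vs_link3,
       cat(sprintf("  link 2 vs link 3:           t(%d) = %.*g, p = %.*g\n",
                   df, digits, t, digits, p)))
  with(x$anova,
       cat(sprintf("  RM-ANOVA over bins:         F(%d, %d) = %.*g, p = %.*g\n",
                   df1, df2, digits, F, digits, p)))
  invisible(x)
}
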