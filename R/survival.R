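# ---- H-score -----------------------------------------------------------

#' Immunohistochemistry H-score
#'
#' H-score = staining intensity (0-3) x percent positive nuclei (0-100),
#' range 0-300.
#'
#' @param intensity integer in 0..3.
#' @param pct_positive percentage in [0, 100].
#' @return list(intensity, pct_positive, h).
#' @export
compute_hscore <- function(intensity, pct_positive) {
  if (any(!intensity %in% 0:3)) stop("intensity must be in {0,1,2,3}")
  if (any(pct_positive < 0 | pct_positive > 100))
    stop("pct_positive must be in [0, 100]")
  list(intensity = intensity, pct_positive = pct_positive,
       h = intensity * pct_positive)
}

# ---- median-unbiased quantile -----------------------------------------

#' Median-unbiased sample quantile (Hyndman-Fan definition 8)
#'
#' Evaluates h = (n + 1/3) p + 1/3 and linearly interpolates between the
#' order statistics x_(floor(h)) and x_(floor(h)+1), clamping to the sample
#' minimum and maximum.
#'
#' @param values numeric vector (non-empty).
#' @param p probability in [0, 1].
#' @return the quantile estimate.
#' @export
hf_quantile <- function(values, p) {
  if (length(values) == 0L) stop("empty input")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  x <- sort(values)
  n <- length(x)
  h <- (n + 1 / 3) * p + 1 / 3
  if (h <= 1) return(x[1L])
  if (h >= n) return(x[n])
  lo <- floor(h)
  x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
}

#' Dichotomize scores at the first quartile
#'
#' Cut = \code{hf_quantile(scores, 0.25)}; scores <= cut are labelled
#' \code{"low"}, others \code{"high"} (the boundary value belongs to the
#' low group).
#'
#' @param scores numeric vector (n >= 4).
#' @return list(cut, group) with \code{group} a factor low/high.
#' @export
dichotomize_first_quartile <- function(scores) {
  if (length(scores) < 4L) stop("need >= 4 values")
  cut <- hf_quantile(scores, 0.25)
  grp <- factor(ifelse(scores <= cut, "low", "high"),
                levels = c("low", "high"))
  if (all(grp == "low"))
    warning("degenerate split: all scores fall in the low group")
  list(cut = cut, group = grp)
}

# ---- survival records --------------------------------------------------

#' Build a survival-record table
#' @param subject_id identifiers; \code{time} in months (> 0);
#'   \code{event} logical/0-1 (TRUE = event observed);
#'   \code{covariates} optional data.frame of numeric covariates.
#' @param time,event vectors as above.
#' @export
survival_records <- function(subject_id, time, event, covariates = NULL) {
  if (any(time <= 0)) stop("non-positive survival time")
  event <- as.logical(event)
  df <- data.frame(subject_id = as.character(subject_id),
                   time = as.numeric(time), event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df
}

#' Read a clinical table (subject_id, time_months, event, covariates...)
#' @param path TSV path.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cov <- df[, setdiff(names(df), need), drop = FALSE]
  survival_records(df$subject_id, df$time_months, df$event,
                   if (ncol(cov)) cov else NULL)
}

# ---- Kaplan-Meier ------------------------------------------------------

#' Kaplan-Meier product-limit estimate with Greenwood log-log 95% CI
#'
#' Survival is estimated at each distinct event time; pointwise 95%
#' confidence limits use the complementary log-log transform of the
#' Greenwood variance (bounded in [0, 1]). Censoring at last follow-up is
#' honoured.
#'
#' @param records survival-record data.frame (time, event).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: time, n_risk, n_event, n_censor, survival, std_err,
#'   ci_low, ci_high (one row per distinct event time).
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  if (nrow(records) == 0L) stop("no records")
  if (any(records$time <= 0)) stop("non-positive survival time")
  t <- records$time; d <- as.logical(records$event)
  ut <- sort(unique(t[d]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- length(ut)
  surv <- numeric(n); vsum <- 0; gw <- numeric(n)
  n_risk <- integer(n); n_event <- integer(n); n_cens <- integer(n)
  s <- 1
  for (i in seq_len(n)) {
    ti <- ut[i]
    n_risk[i] <- sum(t >= ti)
    n_event[i] <- sum(t == ti & d)
    n_cens[i] <- sum(t == ti & !d)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
    vsum <- vsum + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    gw[i] <- vsum
  }
  std_err <- surv * sqrt(gw)
  # log-log CI: S^exp(±z * sqrt(gw)/log S); undefined at S = 0 or 1
  cll_se <- sqrt(gw) / abs(log(surv))
  ci_low <- surv^exp(z * cll_se)
  ci_high <- surv^exp(-z * cll_se)
  deg <- surv <= 0 | surv >= 1 | !is.finite(cll_se)
  ci_low[deg] <- NA_real_; ci_high[deg] <- NA_real_
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_cens, survival = surv, std_err = std_err,
             ci_low = ci_low, ci_high = ci_high)
}

#' Write a KM curve table to TSV
#' @param km output of \code{km_estimate}; \code{path} output file.
#' @param path output path.
#' @export
write_km <- function(km, path) {
  utils::write.table(km, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- log-rank ----------------------------------------------------------

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the event experience of two
#' groups, using the hypergeometric mean and variance at each distinct
#' event time.
#'
#' @param group_a,group_b survival-record data.frames.
#' @return list(chi2, p, observed_a, expected_a).
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) stop("empty group")
  t <- c(group_a$time, group_b$time)
  d <- as.logical(c(group_a$event, group_b$event))
  g <- rep(c(0L, 1L), c(nrow(group_a), nrow(group_b)))
  if (!any(d)) stop("no events in either group")
  ut <- sort(unique(t[d]))
  O <- 0; E <- 0; V <- 0
  for (ti in ut) {
    at_risk <- t >= ti
    n1 <- sum(at_risk & g == 0L); n <- sum(at_risk)
    dtot <- sum(t == ti & d)
    d1 <- sum(t == ti & d & g == 0L)
    O <- O + d1
    E <- E + dtot * n1 / n
    if (n > 1)
      V <- V + dtot * (n1 / n) * (1 - n1 / n) * (n - dtot) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed_a = O, expected_a = E)
}

# ---- optimal cutpoint --------------------------------------------------

#' Maximally selected log-rank cutpoint (single split)
#'
#' Scans all candidate splits at observed score values whose quantile lies
#' inside \code{range}, dichotomizing at score > cut vs <= cut, and returns
#' the split maximizing the log-rank chi-square. The returned \code{p} is
#' the NAIVE log-rank p at the chosen split and is not corrected for the
#' scan; an optional permutation-adjusted p (scores relabelled across
#' subjects) is available via \code{n_perm}.
#'
#' @param scores numeric vector aligned with \code{records} rows (or named
#'   by subject_id).
#' @param records survival-record data.frame.
#' @param range quantile interval searched (default c(0.10, 0.90)).
#' @param n_perm if > 0, number of permutations for the adjusted p.
#' @param seed RNG seed for the permutation.
#' @return list(cut, chi2, p_naive, p_adjusted, n_perm).
#' @export
optimal_cutpoint <- function(scores, records, range = c(0.10, 0.90),
                             n_perm = 0L, seed = 1L) {
  if (!is.null(names(scores))) scores <- scores[records$subject_id]
  if (length(unique(scores)) < 2L) stop("constant scores")
  if (range[1] <= 0 || range[2] >= 1 || range[1] >= range[2])
    stop("range must lie within (0, 1)")
  .max_chi2 <- function(sc) {
    qs <- stats::ecdf(sc)(sc)
    cand <- sort(unique(sc[qs >= range[1] & qs <= range[2]]))
    cand <- cand[cand < max(sc)]   # a split must leave both sides non-empty
    if (length(cand) == 0L) return(NULL)
    best <- c(cut = NA_real_, chi2 = -Inf)
    for (cv in cand) {
      hi <- sc > cv
      lr <- tryCatch(
        logrank_test(records[!hi, , drop = FALSE],
                     records[hi, , drop = FALSE]),
        error = function(e) NULL)
      if (!is.null(lr) && lr$chi2 > best["chi2"])
        best <- c(cut = cv, chi2 = lr$chi2)
    }
    if (!is.finite(best["chi2"])) NULL else best
  }
  obs <- .max_chi2(scores)
  if (is.null(obs)) stop("no candidate split inside the quantile range")
  p_naive <- stats::pchisq(obs["chi2"], 1, lower.tail = FALSE)
  p_adj <- NA_real_
  if (n_perm > 0L) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      mx <- .max_chi2(sample(scores))
      if (!is.null(mx) && mx["chi2"] >= obs["chi2"]) exceed <- exceed + 1L
    }
    p_adj <- (1 + exceed) / (1 + n_perm)
  }
  list(cut = unname(obs["cut"]), chi2 = unname(obs["chi2"]),
       p_naive = unname(p_naive), p_adjusted = p_adj,
       n_perm = as.integer(n_perm))
}

# ---- Cox proportional hazards -----------------------------------------

#' Cox proportional-hazards regression (Efron ties, Newton-Raphson)
#'
#' Maximizes the Cox partial likelihood with Efron's approximation for
#' tied event times by Newton iteration, declaring convergence when the
#' maximum absolute score component falls below 1e-8 (error after 25
#' iterations). Wald and score tests are reported; the score test at
#' beta = 0 for a single binary covariate coincides with the log-rank
#' statistic when event times are untied.
#'
#' @param records survival-record data.frame containing the covariate
#'   columns named in \code{covariate_names}.
#' @param covariate_names character vector of covariate column names.
#' @return list: coef, hr, se, z, p_wald (per covariate), score_chi2,
#'   p_score (global, at beta = 0), loglik, iter, converged,
#'   monotone_likelihood flag.
#' @export
cox_ph <- function(records, covariate_names) {
  X <- as.matrix(records[, covariate_names, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite covariate values")
  if (any(apply(X, 2L, function(v) length(unique(v)) == 1L)))
    stop("constant covariate")
  t <- records$time; d <- as.logical(records$event)
  if (!any(d)) stop("no events")
  p <- ncol(X)
  ut <- sort(unique(t[d]))
  risk_idx <- lapply(ut, function(ti) which(t >= ti))
  death_idx <- lapply(ut, function(ti) which(t == ti & d))

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    for (k in seq_along(ut)) {
      R <- risk_idx[[k]]; D <- death_idx[[k]]; m <- length(D)
      s0R <- sum(w[R]); s1R <- colSums(X[R, , drop = FALSE] * w[R])
      s2R <- crossprod(X[R, , drop = FALSE] * sqrt(w[R]))
      s0D <- sum(w[D]); s1D <- colSums(X[D, , drop = FALSE] * w[D])
      s2D <- crossprod(X[D, , drop = FALSE] * sqrt(w[D]))
      ll <- ll + sum(eta[D])
      sX <- colSums(X[D, , drop = FALSE])
      U <- U + sX
      for (j in seq_len(m) - 1L) {
        c0 <- s0R - (j / m) * s0D
        c1 <- s1R - (j / m) * s1D
        c2 <- s2R - (j / m) * s2D
        ll <- ll - log(c0)
        U <- U - c1 / c0
        I <- I + c2 / c0 - tcrossprod(c1 / c0)
      }
    }
    list(ll = ll, U = U, I = I)
  }

  # score test at beta = 0 (global)
  null_parts <- loglik_parts(numeric(p))
  score_chi2 <- tryCatch(
    drop(t(null_parts$U) %*% solve(null_parts$I, null_parts$U)),
    error = function(e) NA_real_)
  p_score <- stats::pchisq(score_chi2, p, lower.tail = FALSE)

  beta <- numeric(p)
  converged <- FALSE; monotone <- FALSE
  parts <- null_parts
  for (iter in 1:25) {
    if (max(abs(parts$U)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$I, parts$U), error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    # step-halving if the likelihood decreases materially (relative
    # tolerance: near the optimum ll is flat to machine precision)
    lltol <- 1e-9 * (abs(parts$ll) + 1)
    new_beta <- beta + step
    new_parts <- loglik_parts(new_beta)
    halves <- 0L
    while (new_parts$ll < parts$ll - lltol && halves < 10L) {
      step <- step / 2; new_beta <- beta + step
      new_parts <- loglik_parts(new_beta); halves <- halves + 1L
    }
    beta <- new_beta; parts <- new_parts
    if (any(abs(beta) > 15)) { monotone <- TRUE; break }
  }
  if (!converged && !monotone)
    stop("Cox partial-likelihood Newton iteration did not converge")
  if (monotone)
    warning("monotone partial likelihood (possible perfect separation); ",
            "estimates reported at last stable iterate")
  vcov <- tryCatch(solve(parts$I), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  list(coef = stats::setNames(beta, covariate_names),
       hr = stats::setNames(exp(beta), covariate_names),
       se = stats::setNames(se, covariate_names),
       z = stats::setNames(z, covariate_names),
       p_wald = stats::setNames(2 * stats::pnorm(-abs(z)), covariate_names),
       score_chi2 = score_chi2, p_score = p_score,
       loglik = parts$ll, iter = iter, converged = converged,
       monotone_likelihood = monotone, vcov = vcov)
}
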