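# Negative binomial log-likelihood with mean mu and dispersion theta
.nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu) +
                                                      (y == 0)))
}

# one IRLS pass for log-link NB regression at fixed theta
.nb_irls <- function(y, X, theta, beta = NULL, offset = NULL,
                     max_iter = 50, tol = 1e-10) {
  if (is.null(offset)) offset <- rep(0, length(y))
  if (is.null(beta)) {
    eta <- log(y + 0.5)
    beta <- qr.solve(X, eta - offset)
  }
  for (it in seq_len(max_iter)) {
    # clamp the linear predictor: keeps the solve well-conditioned when a
    # stratum has all-zero counts (its coefficient diverges to -Inf)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -15), 15)
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X
    beta_new <- tryCatch(solve(A, XtW %*% z), error = function(e)
      solve(A + diag(1e-8 * max(diag(A)), ncol(A)), XtW %*% z))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- drop(beta_new); break
    }
    beta <- drop(beta_new)
  }
  names(beta) <- colnames(X)
  beta
}

# ML update of theta given the fitted means, on a log grid-free search
.nb_theta_ml <- function(y, mu, lower = 1e-3, upper = 1e6) {
  f <- function(lt) .nb_loglik(y, mu, exp(lt))
  opt <- optimize(f, c(log(lower), log(upper)), maximum = TRUE,
                  tol = 1e-10)
  exp(opt$maximum)
}

#' Fit a negative-binomial GLM for mutation burden
#'
#' Count regression with log link and NB2 variance mu + mu^2/theta, fitted
#' by alternating iteratively reweighted least squares for the coefficients
#' at fixed theta with maximum-likelihood updates of theta at fixed
#' coefficients, until the relative log-likelihood change falls below
#' `tol` (default 1e-8) or `max_iter` alternations. Dispersion estimates
#' hitting the upper bound 1e6 indicate an effectively Poisson fit and are
#' reported as such, not as failures. Wald tests are reported per
#' coefficient; because theta is estimated, the Wald statistics (and the
#' [confint()] method) are referred to a t distribution on the residual
#' degrees of freedom rather than the normal, which calibrates small
#' cohorts. This is the enrichment test used to compare somatic
#' variant burden across disease groups with sex, age, origin and log
#' total coverage as covariates.
#'
#' @param formula model formula; the response is a count column of a
#'   burden table.
#' @param data data frame (typically from [build_burden()]).
#' @param theta optional fixed dispersion; when supplied no theta updates
#'   are performed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum outer alternations.
#' @return an object of class `nb_glm` with components coefficients, se,
#'   z, p_value, theta, vcov, fitted, linear_predictors, loglik,
#'   converged, iter, model (the model frame), terms, xlevels.
#' @examples
#' d <- data.frame(y = c(4, 6, 5, 5))
#' fit <- nb_glm(y ~ 1, d)
#' exp(coef(fit))  # fitted mean = 5
#' @export
nb_glm <- function(formula, data, theta = NULL, tol = 1e-8,
                   max_iter = 100L) {
  mf <- model.frame(formula, data, na.action = na.fail)
  y <- model.response(mf)
  if (any(y < 0) || any(y != round(y)))
    .stopf("response must be non-negative integer counts")
  X <- model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- rep(0, length(y))
  fixed_theta <- !is.null(theta)
  th <- if (fixed_theta) theta else {
    # method-of-moments start
    mu0 <- mean(y)
    v0 <- stats::var(y)
    if (is.na(v0) || v0 <= mu0) 1e6 else min(max(mu0^2 / (v0 - mu0), 1e-3),
                                             1e6)
  }
  beta <- .nb_irls(y, X, th, offset = off)
  mu <- exp(pmin(pmax(drop(X %*% beta) + off, -15), 15))
  ll <- .nb_loglik(y, mu, th)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (!fixed_theta) th <- .nb_theta_ml(y, mu)
    beta <- .nb_irls(y, X, th, beta, offset = off)
    mu <- exp(pmin(pmax(drop(X %*% beta) + off, -15), 15))
    ll_new <- .nb_loglik(y, mu, th)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  w <- mu / (1 + mu / th)
  A <- t(X * w) %*% X
  vc <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8 * max(diag(A)), ncol(A))))
  se <- sqrt(diag(vc))
  z <- beta / se
  df_res <- length(y) - ncol(X)
  # theta is estimated, so Wald statistics are referred to a t distribution
  # on the residual degrees of freedom (small-sample calibration)
  p <- 2 * stats::pt(-abs(z), df = max(df_res, 1))
  structure(list(coefficients = beta, se = se, z = z, p_value = p,
                 df_residual = df_res,
                 theta = th, theta_fixed = fixed_theta, vcov = vc,
                 fitted = mu, linear_predictors = log(mu), y = y,
                 loglik = ll, converged = converged, iter = it,
                 model = mf, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 call = match.call()),
            class = "nb_glm")
}

#' @export
print.nb_glm <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\ntheta = %.4g%s, logLik = %.3f, converged: %s\n", x$theta,
              if (x$theta >= 1e6) " (at upper bound; ~Poisson)" else "",
              x$loglik, x$converged))
  invisible(x)
}

#' @export
summary.nb_glm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p_value)
  out <- list(coefficients = tab, theta = object$theta,
              loglik = object$loglik, converged = object$converged,
              call = object$call)
  class(out) <- "summary.nb_glm"
  out
}

#' @export
print.summary.nb_glm <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\ntheta = %.4g, logLik = %.3f, converged: %s\n", x$theta,
              x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.nb_glm <- function(object, ...) object$coefficients

# refit with column j of the design fixed at b0 (absorbed into the offset),
# theta re-estimated; returns the constrained log-likelihood
.nb_profile_ll <- function(object, j, b0, max_iter = 50) {
  mf <- object$model
  X <- model.matrix(object$terms, mf)
  y <- object$y
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- rep(0, length(y))
  off <- off + b0 * X[, j]
  X0 <- X[, -j, drop = FALSE]
  th <- object$theta
  beta <- NULL
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    beta <- .nb_irls(y, X0, th, beta, offset = off)
    mu <- exp(pmin(pmax(drop(X0 %*% beta) + off, -15), 15))
    if (!object$theta_fixed) th <- .nb_theta_ml(y, mu)
    ll_new <- .nb_loglik(y, mu, th)
    if (abs(ll_new - ll) < 1e-8 * (abs(ll_new) + 1e-8)) return(ll_new)
    ll <- ll_new
  }
  ll
}

#' Confidence intervals for nb_glm coefficients
#'
#' Profile-likelihood intervals by default (inverting the likelihood-ratio
#' test with theta re-estimated along the profile, the convention of NB
#' model fitters); `method = "wald"` gives t-based Wald intervals on the
#' residual degrees of freedom.
#'
#' @param object an [nb_glm()] fit.
#' @param parm coefficient names (default all).
#' @param level confidence level.
#' @param method "profile" (default) or "wald".
#' @param ... unused.
#' @return matrix of lower/upper bounds.
#' @export
confint.nb_glm <- function(object, parm, level = 0.95,
                           method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  if (method == "wald") {
    q <- stats::qt(1 - (1 - level) / 2, df = max(object$df_residual, 1))
    out <- cbind(cf[parm] - q * object$se[parm],
                 cf[parm] + q * object$se[parm])
  } else {
    # F-calibrated likelihood-ratio inversion: with theta estimated on a
    # small cohort the LR statistic is referred to F(1, df_residual)
    # rather than chi-squared (quasi-likelihood small-sample practice)
    crit <- stats::qf(level, 1, max(object$df_residual, 1)) / 2
    out <- t(vapply(parm, function(nm) {
      j <- match(nm, names(cf))
      dev <- function(b0) (object$loglik - .nb_profile_ll(object, j, b0)) -
        crit
      step <- max(object$se[j], 1e-3)
      find <- function(dir) {
        hi <- cf[j] + dir * 4 * step
        for (k in 1:8) {
          if (dev(hi) >= 0) break
          hi <- cf[j] + dir * (4 + 4 * k) * step
        }
        if (dev(hi) < 0) return(hi)  # bound not reached; report the span
        stats::uniroot(dev, sort(c(cf[j], hi)), tol = 1e-5)$root
      }
      c(find(-1), find(1))
    }, numeric(2)))
  }
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  out
}

#' Likelihood-ratio test for one nb_glm coefficient
#'
#' Drops a single design column (fixing its coefficient at zero), refits
#' with theta re-estimated, and refers the likelihood-ratio statistic to
#' F(1, residual df) — the small-sample calibration used in
#' quasi-likelihood count frameworks — matching the default profile
#' [confint()] inversion.
#'
#' @param object an [nb_glm()] fit.
#' @param coef_name name of the coefficient (a design-matrix column).
#' @return list with statistic (the LR statistic) and p_value.
#' @export
nb_glm_lrt <- function(object, coef_name) {
  j <- match(coef_name, names(object$coefficients))
  if (is.na(j)) .stopf("no coefficient '%s'", coef_name)
  ll0 <- .nb_profile_ll(object, j, 0)
  stat <- max(2 * (object$loglik - ll0), 0)
  list(statistic = stat,
       p_value = stats::pf(stat, 1, max(object$df_residual, 1),
                           lower.tail = FALSE))
}

#' @export
vcov.nb_glm <- function(object, ...) object$vcov

#' @export
logLik.nb_glm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + !object$theta_fixed,
            class = "logLik")
}

#' @export
fitted.nb_glm <- function(object, ...) object$fitted

#' @export
predict.nb_glm <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictors
  } else {
    tt <- delete.response(object$terms)
    mf <- model.frame(tt, newdata, xlev = object$xlevels)
    X <- model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") exp(eta) else eta
}

#' @export
residuals.nb_glm <- function(object,
                             type = c("pearson", "deviance", "response"),
                             ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted; th <- object$theta
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu + mu^2 / th),
    deviance = {
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                  (y + th) * log((y + th) / (mu + th)))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
}

#' @export
simulate.nb_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, rnbinom(n, mu = object$fitted,
                                               size = object$theta)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Build a per-sample burden table
#'
#' Counts somatic-classified calls per sample in total, per allele-
#' frequency bin (left-open, right-closed), and per gene, joined to the
#' sample metadata. Somatic calls with VAF outside every bin are counted
#' in the total only, and their number is reported in the
#' `n_unbinned` attribute.
#'
#' @param calls_by_sample named list (by sample_id) of classified,
#'   annotated call data frames.
#' @param meta sample metadata data frame (sample_id, group, sex, age,
#'   origin, total_coverage).
#' @param af_bin_edges strictly increasing bin edges inside (0, 0.5)
#'   (default 0.015, 0.05, 0.15, 0.35).
#' @param genes panel gene symbols; defaults to genes seen in the calls.
#' @return data frame: one row per sample with total, bin_* and gene_*
#'   count columns plus the metadata columns. Samples without calls keep
#'   an all-zero row.
#' @export
build_burden <- function(calls_by_sample, meta,
                         af_bin_edges = c(0.015, 0.05, 0.15, 0.35),
                         genes = NULL) {
  stopifnot(all(diff(af_bin_edges) > 0), af_bin_edges[1] > 0,
            af_bin_edges[length(af_bin_edges)] < 0.5)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(calls_by_sample, function(d)
      d$gene_symbol[!is.na(d$gene_symbol)]))))
  }
  genes <- as.character(genes)
  nb <- length(af_bin_edges) - 1
  bin_names <- sprintf("bin_%g_%g", af_bin_edges[-length(af_bin_edges)],
                       af_bin_edges[-1])
  n_unbinned <- 0L
  rows <- lapply(meta$sample_id, function(sid) {
    d <- calls_by_sample[[sid]]
    som <- if (is.null(d) || nrow(d) == 0) NULL else
      d[d$classification == "somatic", , drop = FALSE]
    total <- if (is.null(som)) 0L else nrow(som)
    bins <- setNames(integer(nb), bin_names)
    gene_counts <- setNames(integer(length(genes)),
                            paste0("gene_", genes, recycle0 = TRUE))
    if (!is.null(som) && nrow(som) > 0) {
      b <- findInterval(som$vaf, af_bin_edges, left.open = TRUE,
                        rightmost.closed = FALSE)
      inbin <- b >= 1 & b <= nb & som$vaf > af_bin_edges[1] &
        som$vaf <= af_bin_edges[nb + 1]
      n_unbinned <<- n_unbinned + sum(!inbin)
      for (k in which(inbin)) bins[b[k]] <- bins[b[k]] + 1L
      if ("gene_symbol" %in% names(som)) {
        for (g in som$gene_symbol[!is.na(som$gene_symbol)]) {
          nm <- paste0("gene_", g)
          if (nm %in% names(gene_counts))
            gene_counts[nm] <- gene_counts[nm] + 1L
        }
      }
    }
    as.data.frame(c(list(sample_id = sid, total = total), as.list(bins),
                    as.list(gene_counts)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, meta, by = "sample_id", sort = FALSE)
  attr(out, "af_bin_edges") <- af_bin_edges
  attr(out, "n_unbinned") <- n_unbinned
  out
}

#' Group-burden enrichment test (NB GLM with covariates)
#'
#' Fits `count ~ group + sex + age + origin + log(total_coverage)` by
#' [nb_glm()] with the control group as reference level and returns the
#' fit. Covariates absent from the table (or constant) are dropped.
#'
#' @param burden a [build_burden()] table.
#' @param response name of the count column to model (default "total").
#' @param reference reference group level (default "control").
#' @return an `nb_glm` fit; group coefficients are log burden ratios
#'   versus the reference group.
#' @export
burden_test <- function(burden, response = "total",
                        reference = "control") {
  burden$group <- stats::relevel(factor(burden$group), ref = reference)
  # origin reference = most frequent level, for determinism
  if ("origin" %in% names(burden)) {
    tab <- sort(table(burden$origin), decreasing = TRUE)
    burden$origin <- stats::relevel(factor(burden$origin),
                                    ref = names(tab)[1])
  }
  covs <- c("sex", "age", "origin")
  covs <- covs[vapply(covs, function(v)
    v %in% names(burden) && length(unique(burden[[v]])) > 1, logical(1))]
  if ("total_coverage" %in% names(burden))
    covs <- c(covs, "log(total_coverage)")
  # add covariates only while the design stays full rank with spare
  # residual degrees of freedom; small cohorts fall back to group-only
  terms_in <- "group"
  for (v in covs) {
    cand <- c(terms_in, v)
    X <- model.matrix(stats::as.formula(paste("~", paste(cand,
                                                         collapse = " + "))),
                      burden)
    if (qr(X)$rank == ncol(X) && nrow(X) > ncol(X) + 1) terms_in <- cand
  }
  rhs <- paste(terms_in, collapse = " + ")
  nb_glm(stats::as.formula(paste(response, "~", rhs)), burden)
}

#' Group summary and two-sample t-test of total burden
#'
#' Reports per-group mean and sample standard deviation of the total
#' variant count and the two-sided two-sample t-test (Welch by default)
#' between two groups.
#'
#' @param burden a [build_burden()] table (needs `total` and `group`).
#' @param group_a,group_b the two group labels to compare.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list with mu (named means), sigma (named SDs), t, df, p_value,
#'   method.
#' @export
summary_t_test <- function(burden, group_a = "sALS", group_b = "control",
                           var_equal = FALSE) {
  xa <- burden$total[burden$group == group_a]
  xb <- burden$total[burden$group == group_b]
  if (length(xa) < 2 || length(xb) < 2)
    .stopf("need >= 2 samples per group")
  tt <- t.test(xa, xb, var.equal = var_equal)
  list(mu = setNames(c(mean(xa), mean(xb)), c(group_a, group_b)),
       sigma = setNames(c(sd(xa), sd(xb)), c(group_a, group_b)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = tt$method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; q-values are monotone in p and
#' capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values (same length/order as `p`).
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must be in [0,1]")
  p.adjust(p, method = "BH")
}

#' Per-gene burden ratios with NB GLM tests
#'
#' For every panel gene, the ratio of mean somatic counts between two
#' groups with a pseudo-count (default 0.5) guarding sparse genes, plus a
#' per-gene [nb_glm()] Wald test of the group effect and BH-adjusted
#' q-values across genes.
#'
#' @param burden a [build_burden()] table containing gene_* columns.
#' @param group_a,group_b groups to compare (ratio = a over b).
#' @param pseudo pseudo-count added to both means (default 0.5).
#' @param covariates include the standard covariates in the per-gene GLM
#'   (default FALSE: group-only, appropriate for sparse per-gene counts).
#' @return data frame: gene, mean_a, mean_b, ratio, p_value, q_value.
#' @export
gene_burden_ratio <- function(burden, group_a = "sALS",
                              group_b = "control", pseudo = 0.5,
                              covariates = FALSE) {
  gcols <- grep("^gene_", names(burden), value = TRUE)
  if (length(gcols) == 0) .stopf("burden table has no gene_ columns")
  sub <- burden[burden$group %in% c(group_a, group_b), , drop = FALSE]
  sub$group <- stats::relevel(factor(sub$group), ref = group_b)
  rows <- lapply(gcols, function(gc) {
    ya <- sub[[gc]][sub$group == group_a]
    yb <- sub[[gc]][sub$group == group_b]
    p <- tryCatch({
      f <- if (covariates) stats::as.formula(paste(
        gc, "~ group + sex + age + log(total_coverage)")) else
          stats::as.formula(paste(gc, "~ group"))
      fit <- nb_glm(f, sub)
      unname(fit$p_value[paste0("group", group_a)])
    }, error = function(e) NA_real_)
    data.frame(gene = sub("^gene_", "", gc),
               mean_a = mean(ya), mean_b = mean(yb),
               ratio = (mean(ya) + pseudo) / (mean(yb) + pseudo),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- fdr_adjust(out$p_value)
  attr(out, "pseudo") <- pseudo
  out
}
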