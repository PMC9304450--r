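# Right-censored Tobit regression of lifespan on biomarkers, the
# pseudo-r-squared goodness-of-fit, signed correlation maps, and
# two-timepoint delta biomarkers.
#
# The censored Gaussian likelihood is maximized here directly (quasi-Newton
# on (beta, log sigma) from an OLS start) rather than delegated to a survival
# package, so the estimator is fully under test; survreg serves only as an
# independent oracle in the test suite.

#' Per-subject cohort table
#'
#' Validates a cohort data.frame of biomarkers and right-censored lifespans.
#' In the emulated study design, subjects still alive at the censor level
#' (default 25 months) were euthanized, so \code{censored == 1} implies
#' \code{lifespan == y_max}; that consistency check can be relaxed with
#' \code{strict = FALSE}.
#'
#' @param data data.frame with columns \code{subject_id},
#'   \code{lifespan_months}, \code{censored} (0/1) and biomarker columns.
#' @param y_max censor level (months, default 25).
#' @param strict enforce censored == (lifespan == y_max).
#' @return the validated data.frame with attributes \code{y_max}.
#' @export
cohort_table <- function(data, y_max = 25, strict = TRUE) {
  need <- c("subject_id", "lifespan_months", "censored")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) < 3) stop("need >= 3 subjects")
  if (any(data$lifespan_months > y_max + 1e-9))
    stop("lifespans exceed the censor level y_max")
  if (strict) {
    at_max <- abs(data$lifespan_months - y_max) < 1e-9
    if (any(as.logical(data$censored) != at_max))
      stop("censored flag inconsistent with lifespan == y_max; ",
           "use strict = FALSE to override")
  }
  attr(data, "y_max") <- y_max
  data
}

tobit_negloglik <- function(par, x, y, censored, y_max) {
  k <- length(par)
  beta <- par[-k]
  sigma <- exp(par[k])
  eta <- drop(x %*% beta)
  ll <- numeric(length(y))
  unc <- !censored
  ll[unc] <- dnorm(y[unc], eta[unc], sigma, log = TRUE)
  ll[censored] <- pnorm((y_max - eta[censored]) / sigma, lower.tail = FALSE,
                        log.p = TRUE)
  -sum(ll)
}

#' Fit a right-censored Tobit regression
#'
#' Maximum likelihood for the latent model \eqn{Y^* = X\beta + u},
#' \eqn{u \sim N(0, \sigma^2)}, observed as \eqn{Y = \min(Y^*, Y_{max})}
#' with a censoring indicator. Uncensored observations contribute
#' \eqn{\log\phi((y - X\beta)/\sigma) - \log\sigma}; censored ones
#' \eqn{\log(1 - \Phi((Y_{max} - X\beta)/\sigma))}. Optimization is BFGS on
#' \eqn{(\beta, \log\sigma)} from the OLS start, so the fit is deterministic
#' given the data.
#'
#' @param x predictor vector (or matrix without intercept column).
#' @param y response (lifespan, months).
#' @param censored logical/0-1 right-censoring flags.
#' @param y_max censor level (default 25).
#' @return object of class \code{tobit_fit}: \code{beta} (intercept first),
#'   \code{sigma}, \code{loglik}, \code{pseudo_r2} (default convention, see
#'   \code{\link{pseudo_r2}}), \code{slope_sign}, \code{converged},
#'   \code{n_obs}, \code{n_censored}, \code{vcov}.
#' @export
tobit_fit <- function(x, y, censored, y_max = 25) {
  x <- as.matrix(x)
  censored <- as.logical(censored)
  if (length(y) < 3) stop("need >= 3 observations")
  if (all(censored)) stop("all observations are censored")
  if (any(apply(x, 2, var) < 1e-14)) stop("constant predictor")
  if (length(y) != nrow(x) || length(censored) != length(y))
    stop("x, y, censored lengths differ")
  X <- cbind(intercept = 1, x)

  ols <- stats::lm.fit(X, y)
  s0 <- sqrt(mean(ols$residuals^2))
  start <- c(ols$coefficients, log(max(s0, 1e-3)))

  opt <- optim(start, tobit_negloglik, x = X, y = y, censored = censored,
               y_max = y_max, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12), hessian = TRUE)
  k <- length(opt$par)
  beta <- opt$par[-k]
  sigma <- unname(exp(opt$par[k]))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  fitted <- drop(X %*% beta)

  fit <- structure(list(beta = beta, sigma = sigma, loglik = -opt$value,
                        fitted = fitted, y = y, censored = censored,
                        y_max = y_max,
                        slope_sign = sign(beta[2]),
                        converged = opt$convergence == 0,
                        n_obs = length(y), n_censored = sum(censored),
                        vcov = vc),
                   class = "tobit_fit")
  fit$pseudo_r2 <- pseudo_r2(fit)
  fit
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf(
    "Tobit fit: n = %d (%d censored at %.3g), sigma = %.4g, loglik = %.4g\n",
    x$n_obs, x$n_censored, x$y_max, x$sigma, x$loglik))
  print(signif(x$beta, 5))
  cat("pseudo-r2 =", signif(x$pseudo_r2, 4), "\n")
  invisible(x)
}

#' Pseudo-r-squared for a Tobit fit
#'
#' Two conventions are provided. \code{"correlation"} (default) is the
#' squared Pearson correlation between the fitted linear predictor
#' \eqn{\hat Y = X\hat\beta} and the observed (censored-coded) response;
#' it recovers the standard OLS r-squared exactly when no observation is
#' censored, and reproduces the values reported for the reference mouse
#' cohort. \code{"latent"} is the McKelvey--Zavoina latent-variance ratio
#' \deqn{r^2 = \frac{\sum(\hat Y - \bar{\hat Y})^2}
#' {\sum(\hat Y - \bar{\hat Y})^2 + N\hat\sigma^2},} which also recovers the
#' OLS r-squared (with the MLE error variance) in the uncensored limit.
#' Both lie in \code{[0, 1]} and are invariant to affine predictor rescaling.
#'
#' @param fit a \code{\link{tobit_fit}}.
#' @param method \code{"correlation"} or \code{"latent"}.
#' @return pseudo-r-squared in \code{[0, 1]}.
#' @export
pseudo_r2 <- function(fit, method = c("correlation", "latent")) {
  stopifnot(inherits(fit, "tobit_fit"))
  method <- match.arg(method)
  yhat <- fit$fitted
  if (var(yhat) < 1e-14 || var(fit$y) < 1e-14) {
    warning("degenerate variance; pseudo-r2 set to 0")
    return(0)
  }
  if (method == "correlation") {
    cor(yhat, fit$y)^2
  } else {
    ssf <- sum((yhat - mean(yhat))^2)
    ssf / (ssf + fit$n_obs * fit$sigma^2)
  }
}

#' Signed biomarker correlation map
#'
#' For each biomarker against the (right-censored) lifespan column, fits a
#' univariate Tobit regression and records the pseudo-r-squared with the
#' sign of the fitted slope; for biomarker--biomarker pairs (both
#' uncensored) plain OLS r-squared with the slope sign is used. The
#' diagonal is +1. Lifespan cells are computed only with lifespan as the
#' dependent variable (documented asymmetry of the Tobit direction).
#'
#' @param table a \code{\link{cohort_table}}.
#' @param variables biomarker column names; default every numeric column
#'   except ids and lifespan bookkeeping.
#' @param lifespan_col name of the lifespan column.
#' @param r2_method pseudo-r2 convention, see \code{\link{pseudo_r2}}.
#' @return object of class \code{correlation_map}: \code{r2} and \code{sign}
#'   matrices (variables + lifespan), \code{method} matrix ("tobit", "ols" or
#'   "self"), \code{n_tests}.
#' @export
correlation_map <- function(table, variables = NULL,
                            lifespan_col = "lifespan_months",
                            r2_method = "correlation") {
  y_max <- attr(table, "y_max")
  if (is.null(y_max)) y_max <- 25
  if (is.null(variables)) {
    drop_cols <- c("subject_id", lifespan_col, "censored", "timepoint")
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
    variables <- setdiff(variables, drop_cols)
  }
  miss <- setdiff(c(variables, lifespan_col, "censored"), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(variables) < 2) stop("need >= 2 variables")

  all_vars <- c(variables, "LS")
  m <- length(all_vars)
  r2 <- matrix(NA_real_, m, m, dimnames = list(all_vars, all_vars))
  sg <- r2
  meth <- matrix("", m, m, dimnames = list(all_vars, all_vars))
  n_tests <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) { r2[i, j] <- 1; sg[i, j] <- 1; meth[i, j] <- "self"; next }
      vi <- all_vars[i]; vj <- all_vars[j]
      if (vi == "LS" || vj == "LS") {
        xv <- table[[if (vi == "LS") vj else vi]]
        fit <- tobit_fit(xv, table[[lifespan_col]], table$censored, y_max)
        r2[i, j] <- pseudo_r2(fit, r2_method)
        sg[i, j] <- fit$slope_sign
        meth[i, j] <- "tobit"
      } else {
        o <- lm(table[[vi]] ~ table[[vj]])
        r2[i, j] <- summary(o)$r.squared
        sg[i, j] <- sign(coef(o)[2])
        meth[i, j] <- "ols"
      }
      n_tests <- n_tests + 1L
    }
  }
  structure(list(r2 = r2, sign = sg, method = meth, n_tests = n_tests,
                 r2_method = r2_method),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("Signed correlation map (", x$n_tests, " regressions, no multiplicity",
      " correction)\n", sep = "")
  print(round(x$r2 * x$sign, 3))
  invisible(x)
}

#' Write a correlation map (CSV matrix + JSON manifest)
#' @param map a \code{\link{correlation_map}}.
#' @param csv_path signed-r2 matrix CSV.
#' @param json_path manifest with per-cell method and the r2 convention.
#' @export
write_correlation_map <- function(map, csv_path, json_path = NULL) {
  write.csv(map$r2 * map$sign, csv_path, row.names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(r2_method = map$r2_method, n_tests = map$n_tests,
           method = apply(map$method, 1, as.list)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Two-timepoint absolute biomarker change
#'
#' \eqn{\Delta x = |x(t_2) - x(t_1)|} per subject per biomarker, columns
#' renamed \code{delta_<name>}.
#'
#' @param table_t1,table_t2 data.frames with \code{subject_id} and shared
#'   biomarker columns (e.g. two and six months of age).
#' @param variables biomarker columns; default all shared numeric columns
#'   except ids/lifespan bookkeeping.
#' @return data.frame: \code{subject_id} plus \code{delta_*} columns.
#' @export
delta_biomarkers <- function(table_t1, table_t2, variables = NULL) {
  if (is.null(variables)) {
    shared <- intersect(names(table_t1), names(table_t2))
    variables <- shared[vapply(table_t1[shared], is.numeric, logical(1))]
    variables <- setdiff(variables,
                         c("subject_id", "lifespan_months", "censored",
                           "timepoint"))
  }
  unmatched <- c(setdiff(table_t1$subject_id, table_t2$subject_id),
                 setdiff(table_t2$subject_id, table_t1$subject_id))
  if (length(unmatched))
    stop("unmatched subject ids: ", paste(unique(unmatched), collapse = ", "))
  t2 <- table_t2[match(table_t1$subject_id, table_t2$subject_id), ]
  out <- data.frame(subject_id = table_t1$subject_id)
  for (v in variables)
    out[[paste0("delta_", v)]] <- abs(t2[[v]] - table_t1[[v]])
  out
}
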