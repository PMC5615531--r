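#' Binomial logistic regression by iteratively reweighted least squares
#'
#' Fits `log(p / (1 - p)) = X beta` to a binary outcome by maximizing the
#' Bernoulli log-likelihood with Newton scoring (IRLS), with step-halving
#' whenever a step would decrease the log-likelihood. Standard errors come
#' from the inverse observed information `(X' W X)^{-1}` at the optimum
#' (observed and expected information coincide for the canonical logit
#' link). Convergence is declared when `max |delta beta| < tol` within
#' `max_iter` iterations; diverging coefficients (a symptom of complete or
#' quasi-complete separation) are flagged as non-converged rather than
#' silently reported.
#'
#' @param formula model formula; the response must be 0/1 (or logical).
#' @param data data.frame containing the variables. Rows with missing values
#'   in any model variable are dropped (complete-case analysis); the count
#'   is kept in the fit.
#' @param tol convergence tolerance on the coefficient update (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return an object of class `irls_logit`: list with `coefficients`, `se`,
#'   `vcov`, `converged`, `n_used`, `n_dropped`, `loglik`, `loglik_trace`,
#'   `fitted`, `y`, `x`, `terms`, `iter`, `call`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.3), x = rnorm(200))
#' f <- irls_logit(y ~ x, d)
#' summary(f)
#' @export
irls_logit <- function(formula, data, tol = 1e-8, max_iter = 100L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n_dropped <- nrow(data) - nrow(X)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one case and one control")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  p_ll <- function(eta) {
    p <- stats::plogis(eta)
    list(p = p, ll = sum(stats::dbinom(y, 1, p, log = TRUE)))
  }
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y))   # intercept start at the marginal odds
  cur <- p_ll(drop(X %*% beta))
  trace <- cur$ll
  converged <- FALSE
  warned <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    w <- cur$p * (1 - cur$p)
    H <- crossprod(X, X * w)
    g <- crossprod(X, y - cur$p)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) {   # weights collapsed: (quasi-)separation
      converged <- FALSE
      warned <- TRUE
      warning("information matrix singular at iteration ", it,
              ": possible (quasi-)complete separation")
      break
    }
    step <- 1
    repeat {                           # step-halving: never decrease loglik
      cand <- beta + step * delta
      new <- p_ll(drop(X %*% cand))
      if (new$ll >= cur$ll - 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    beta <- drop(cand)
    cur <- new
    trace <- c(trace, cur$ll)
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (max(abs(beta)) > 30) {
    converged <- FALSE
    if (!warned)
      warning("coefficients diverging: possible (quasi-)complete separation")
  }
  w <- cur$p * (1 - cur$p)
  V <- tryCatch(solve(crossprod(X, X * w)), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  names(beta) <- colnames(X)
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = se, vcov = V,
                 converged = converged, n_used = nrow(X),
                 n_dropped = n_dropped, loglik = cur$ll,
                 loglik_trace = trace, fitted = cur$p, y = y, x = X,
                 terms = attr(mf, "terms"), iter = it,
                 call = match.call()),
            class = "irls_logit")
}

#' @export
print.irls_logit <- function(x, ...) {
  cat("Binomial logistic regression (IRLS)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d (%d dropped as incomplete), cases = %d, iterations = %d%s\n",
              x$n_used, x$n_dropped, sum(x$y), x$iter,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.irls_logit <- function(object, ...) object$coefficients

#' @export
vcov.irls_logit <- function(object, ...) object$vcov

#' @export
logLik.irls_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @export
confint.irls_logit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.irls_logit <- function(object, newdata = NULL,
                               type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    drop(object$x %*% object$coefficients)
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    na.action = stats::na.pass))
    drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.irls_logit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  p <- object$fitted; y <- object$y
  if (type == "pearson") return((y - p) / sqrt(p * (1 - p)))
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' @export
simulate.irls_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n_used, 1,
                                                     object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.irls_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab,
                 or = adjusted_ors(object, .allow_nonconverged = TRUE)),
            class = "summary.irls_logit")
}

#' @export
print.summary.irls_logit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nOdds ratios (95% Wald CI):\n")
  print(x$or)
  cat(sprintf("\nlog-likelihood: %.3f\n", x$fit$loglik))
  invisible(x)
}

#' Adjusted odds ratios with 95 percent Wald intervals
#'
#' Per non-intercept term of a fitted logistic model: `OR = exp(beta)`,
#' `CI = exp(beta +/- 1.96 se)`. Continuous terms are per unit of their
#' modelling scale (percentage points for the built-environment measures),
#' so a printed OR of 1.03 reads "3% higher odds per 1-point increase".
#'
#' @param fit an [irls_logit()] fit (must have converged).
#' @param level confidence level (default 0.95).
#' @param .allow_nonconverged internal; summary() uses it to display
#'   non-converged fits.
#' @return an `or_table` data.frame: `term`, `or`, `ci_low`, `ci_high`,
#'   `significant` (CI excludes 1).
#' @export
adjusted_ors <- function(fit, level = 0.95, .allow_nonconverged = FALSE) {
  if (!fit$converged && !.allow_nonconverged)
    stop("fit did not converge; odds ratios not reported")
  keep <- setdiff(names(fit$coefficients), "(Intercept)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients[keep]; s <- fit$se[keep]
  or_table(term = keep, or = exp(b), ci_low = exp(b - z * s),
           ci_high = exp(b + z * s))
}

#' Construct an odds-ratio result table
#'
#' Shared container for crude and adjusted OR results, also handy for
#' entering published OR tables. Significance is defined as the 95% CI
#' excluding 1.
#'
#' @param term character vector of variable names.
#' @param or,ci_low,ci_high odds ratios and their interval bounds.
#' @return an `or_table` data.frame with a `significant` column.
#' @export
or_table <- function(term, or, ci_low, ci_high) {
  out <- data.frame(term = term, or = or, ci_low = ci_low, ci_high = ci_high,
                    significant = ci_low > 1 | ci_high < 1,
                    row.names = NULL)
  class(out) <- c("or_table", "data.frame")
  out
}

#' @export
print.or_table <- function(x, digits = 2, ...) {
  cat(sprintf("%-28s %s\n", "term", "OR (95% CI)"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s %.*f (%.*f, %.*f)%s\n", x$term[i], digits, x$or[i],
                digits, x$ci_low[i], digits, x$ci_high[i],
                if (isTRUE(x$significant[i])) " *" else ""))
  invisible(x)
}
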