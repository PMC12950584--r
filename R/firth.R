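#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac{1}{2}\log\det I(\beta)}
#' by Newton iteration on the modified score
#' \deqn{U^*(\beta) = \sum_i \{y_i - \pi_i + h_i(\tfrac{1}{2} - \pi_i)\} x_i}
#' with hat values \eqn{h_i} recomputed each iteration from the QR
#' decomposition of the weighted design, and step-halving whenever a step
#' would decrease the penalized likelihood.  The penalty removes the
#' first-order small-sample bias of maximum likelihood and yields finite
#' estimates under complete or quasi-complete separation, which is why it
#' is the method of choice for rare-event clinical models.
#'
#' Convergence requires both `max |U*| < tolerance` and maximal coefficient
#' change `< tolerance`.  Per-coefficient p-values are penalized
#' likelihood-ratio tests by default (each coefficient constrained to zero
#' with the others re-maximized, the penalty always evaluated on the full
#' design); confidence intervals are profile penalized-likelihood intervals
#' by default (see [profile_ci()]), with Wald versions available.
#'
#' @param formula model formula with a strictly binary (0/1) response.
#' @param data data frame with no missing values in the model variables.
#' @param tolerance convergence tolerance on score and coefficient change;
#'   default 1e-8.
#' @param max_iter maximum Newton iterations; default 100.
#' @param ci `"profile"` (default) or `"wald"`.
#' @param pvalues `"plr"` (penalized likelihood ratio, default) or `"wald"`.
#' @param level confidence level for intervals; default 0.95.
#' @return an object of class `firth_fit` with elements `coefficients`,
#'   `se`, `ci` (matrix with attribute `"method"`), `or` (= exp(beta)),
#'   `p`, `pll` (penalized log-likelihood at the optimum), `iter`,
#'   `converged`, `max_score`, and the `terms`/`formula` needed by
#'   [predict_probability()].
#' @examples
#' d <- data.frame(x = c(rep(1, 10), rep(0, 10)),
#'                 y = c(rep(1, 5), rep(0, 15)))
#' fit <- fit_firth(y ~ x, d)
#' coef(fit)  # finite despite the zero cell; equals log 21 for the slope
#' @export
fit_firth <- function(formula, data, tolerance = 1e-8, max_iter = 100,
                      ci = c("profile", "wald"),
                      pvalues = c("plr", "wald"), level = 0.95) {
  ci <- match.arg(ci)
  pvalues <- match.arg(pvalues)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  stopifnot_binary(y, "outcome")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X); n <- nrow(X)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  qr0 <- qr(X)
  if (qr0$rank < p) {
    bad <- colnames(X)[qr0$pivot[(qr0$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  eng <- firth_engine(X, y, tol = tolerance, max_iter = max_iter)
  beta <- eng$beta
  info <- eng$info
  vcov <- solve(info)
  se <- sqrt(diag(vcov))

  if (pvalues == "plr") {
    pvec <- vapply(seq_len(p), function(j) {
      c0 <- firth_engine(X, y, tol = tolerance, max_iter = max_iter,
                         free = setdiff(seq_len(p), j), beta_init = {
                           b <- beta; b[j] <- 0; b
                         })
      stats::pchisq(2 * (eng$pll - c0$pll), df = 1, lower.tail = FALSE)
    }, numeric(1))
  } else {
    pvec <- 2 * stats::pnorm(-abs(beta) / se)
  }
  names(pvec) <- colnames(X)

  fit <- structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vcov, or = stats::setNames(exp(beta), colnames(X)),
    p = pvec, pvalue_method = pvalues,
    pll = eng$pll, iter = eng$iter, converged = eng$converged,
    max_score = eng$max_score, tolerance = tolerance, max_iter = max_iter,
    level = level, n = n, n_events = sum(y),
    terms = attr(mf, "terms"), formula = formula,
    X = X, y = y), class = "firth_fit")

  fit$ci <- if (ci == "profile") profile_ci(fit, level = level)
            else wald_ci(fit, level = level)
  fit
}

# Core maximizer of the penalized likelihood; `free` gives the indices
# updated (others held at beta_init), but the penalty and hat values
# always use the full design, as required for profile likelihoods.
#
# The modified score U* is the exact gradient of the penalized
# log-likelihood, but the Fisher information used for the Newton direction
# is not its exact Hessian, so the scoring iteration converges only
# linearly (and can cycle) close to the optimum.  When it stalls short of
# the tolerance, a BFGS polish with the exact gradient finishes the job.
firth_engine <- function(X, y, tol = 1e-8, max_iter = 100,
                         free = seq_len(ncol(X)), beta_init = NULL) {
  p <- ncol(X); n <- nrow(X)
  beta <- if (is.null(beta_init)) numeric(p) else beta_init

  state <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    W <- pi * (1 - pi)
    Xw <- X * sqrt(W)
    info <- crossprod(Xw)
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))
    ld <- as.numeric(determinant(info, logarithm = TRUE)$modulus)
    list(pll = ll + 0.5 * ld, pi = pi, Xw = Xw, info = info)
  }
  score <- function(st) {
    Q <- qr.Q(qr(st$Xw))
    h <- rowSums(Q^2)
    drop(crossprod(X, y - st$pi + h * (0.5 - st$pi)))
  }

  st <- state(beta)
  if (!length(free)) {
    return(list(beta = beta, pll = st$pll, info = st$info, iter = 0L,
                converged = TRUE, max_score = 0))
  }
  converged <- FALSE
  last_step <- Inf
  max_score <- Inf
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    U <- score(st)
    max_score <- max(abs(U[free]))
    if (max_score < tol && last_step < tol) {
      converged <- TRUE
      break
    }
    delta <- numeric(p)
    info_ff <- st$info[free, free, drop = FALSE]
    delta[free] <- tryCatch(
      solve(info_ff, U[free]),
      error = function(e) {
        # near-degenerate weights: stabilize with a small ridge
        solve(info_ff + diag(1e-8 * (1 + mean(diag(info_ff))),
                             nrow(info_ff)), U[free])
      })
    # cap the step length so early iterations cannot overshoot into
    # regions of vanishing weight (standard in penalized-likelihood fits)
    step_max <- max(abs(delta))
    if (step_max > 5) delta <- delta * (5 / step_max)
    s <- 1
    repeat {
      cand <- beta + s * delta
      st_cand <- state(cand)
      if (st_cand$pll >= st$pll - 1e-10 || s < 1e-6) break
      s <- s / 2
    }
    last_step <- max(abs(s * delta))
    beta <- beta + s * delta
    st <- st_cand
  }

  if (!converged) {
    opt <- stats::optim(
      beta[free],
      fn = function(bf) {
        b <- beta; b[free] <- bf
        -state(b)$pll
      },
      gr = function(bf) {
        b <- beta; b[free] <- bf
        -score(state(b))[free]
      },
      method = "BFGS",
      control = list(maxit = 200, reltol = 1e-16))
    cand <- beta; cand[free] <- opt$par
    st_cand <- state(cand)
    if (st_cand$pll >= st$pll) {
      last_step <- max(abs(cand - beta))
      beta <- cand
      st <- st_cand
    }
    max_score <- max(abs(score(st)[free]))
    converged <- max_score < tol
  }
  list(beta = beta, pll = st$pll, info = st$info, iter = iter,
       converged = converged, max_score = max_score)
}

wald_ci <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = fit$coefficients - z * fit$se,
              upper = fit$coefficients + z * fit$se)
  attr(ci, "method") <- rep("wald", nrow(ci))
  ci
}

#' Profile penalized-likelihood confidence intervals
#'
#' For each coefficient, bounds are the values where twice the drop in
#' penalized log-likelihood from the optimum (re-maximizing over the other
#' coefficients, penalty on the full design) equals the chi-squared
#' quantile, located by root bisection.  If no bracket is found after
#' widening up to 40 standard errors, a Wald interval is substituted with a
#' warning and labelled as such in the `"method"` attribute.
#'
#' @param fit a converged [fit_firth()] object.
#' @param level confidence level; default 0.95.
#' @return a two-column matrix (`lower`, `upper`) with one row per
#'   coefficient and attribute `"method"` (`"profile"` or `"wald"` per row).
#' @export
profile_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "firth_fit"))
  X <- fit$X; y <- fit$y
  p <- length(fit$coefficients)
  target <- fit$pll - stats::qchisq(level, df = 1) / 2
  ci <- matrix(NA_real_, nrow = p, ncol = 2,
               dimnames = list(names(fit$coefficients), c("lower", "upper")))
  method <- rep("profile", p)
  prof <- function(j, value) {
    b0 <- fit$coefficients; b0[j] <- value
    firth_engine(X, y, tol = fit$tolerance, max_iter = fit$max_iter,
                 free = setdiff(seq_len(p), j), beta_init = b0)$pll
  }
  for (j in seq_len(p)) {
    bhat <- fit$coefficients[j]; sej <- fit$se[j]
    for (side in c(-1, 1)) {
      bound <- NA_real_
      for (k in c(2, 4, 8, 16, 40)) {
        lo <- bhat + side * k * sej
        if (prof(j, lo) - target < 0) {
          root <- stats::uniroot(function(b) prof(j, b) - target,
                                 lower = min(bhat, lo), upper = max(bhat, lo),
                                 tol = 1e-6)
          bound <- root$root
          break
        }
      }
      if (is.na(bound)) {
        warning("profile bracket failure for '", names(fit$coefficients)[j],
                "'; Wald interval substituted", call. = FALSE)
        method[j] <- "wald"
        w <- wald_ci(fit, level)
        ci[j, ] <- w[j, ]
        break
      }
      ci[j, if (side < 0) 1 else 2] <- bound
    }
  }
  attr(ci, "method") <- method
  ci
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("Firth penalized logistic regression (n = %d, events = %d)\n",
              x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$or,
                    ci_lower = x$ci[, 1], ci_upper = x$ci[, 2], p = x$p)
  print(round(tab, 4))
  cat(sprintf("penalized logLik %.4f; %d iterations; converged: %s\n",
              x$pll, x$iter, x$converged))
  invisible(x)
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' Predicted event probabilities from a Firth fit
#'
#' @param fit a [fit_firth()] object.
#' @param newdata data frame containing every model covariate; an error
#'   lists any missing variables.
#' @return numeric vector `expit(X beta)`, each strictly inside (0, 1).
#' @export
predict_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "firth_fit"))
  tt <- stats::delete.response(fit$terms)
  need <- all.vars(tt)
  missing <- setdiff(need, names(newdata))
  if (length(missing)) {
    stop("newdata is missing covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                  na.action = stats::na.fail))
  if (!identical(colnames(X), names(fit$coefficients))) {
    stop("covariate columns do not match the fit: expected ",
         paste(names(fit$coefficients), collapse = ", "), call. = FALSE)
  }
  drop(stats::plogis(X %*% fit$coefficients))
}

#' Univariable Firth screening
#'
#' Fits each candidate alone (plus intercept) with [fit_firth()] and
#' returns those with two-sided p below the threshold, preserving input
#' order, together with the full per-candidate report.  Candidates whose
#' fit fails are skipped with a warning.
#'
#' @param data data frame.
#' @param outcome name of the binary outcome column.
#' @param candidates character vector of candidate covariate names.
#' @param threshold p-value threshold; default 0.10.
#' @param ... passed to [fit_firth()].
#' @return a list with `selected` (character), `table` (data frame with
#'   coefficient, OR, CI, p per candidate) and `fits` (named list).
#' @export
univariable_screen <- function(data, outcome, candidates, threshold = 0.10,
                               ...) {
  rows <- list(); fits <- list()
  for (cand in candidates) {
    fit <- tryCatch(
      fit_firth(stats::reformulate(sprintf("`%s`", cand), response = outcome),
                data, ...),
      error = function(e) {
        warning("candidate '", cand, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    j <- 2L  # slope of the single covariate
    rows[[cand]] <- data.frame(
      candidate = cand, coef = unname(fit$coefficients[j]),
      or = unname(fit$or[j]), ci_lower = exp(fit$ci[j, 1]),
      ci_upper = exp(fit$ci[j, 2]), p = unname(fit$p[j]),
      converged = fit$converged, stringsAsFactors = FALSE)
    fits[[cand]] <- fit
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  selected <- tab$candidate[tab$p < threshold]
  list(selected = selected, table = tab, fits = fits, threshold = threshold)
}

#' Apply a p-value screening threshold to a reported univariable table
#'
#' Convenience for published regression tables: returns the variables whose
#' univariable p-value falls strictly below the threshold, preserving the
#' table's order.
#'
#' @param p named numeric vector (or data frame with columns `variable`,
#'   `p`) of univariable p-values.
#' @param threshold default 0.10.
#' @return character vector of selected variable names.
#' @export
screen_by_pvalue <- function(p, threshold = 0.10) {
  if (is.data.frame(p)) {
    stopifnot(all(c("variable", "p") %in% names(p)))
    return(p$variable[p$p < threshold])
  }
  names(p)[p < threshold]
}
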