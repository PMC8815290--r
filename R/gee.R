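# Generalized estimating equations for repeated count outcomes.
#
# Liang-Zeger GEE with a log link, NB2 (or Poisson) variance function,
# exchangeable working correlation estimated by moments from Pearson
# residuals, and robust (sandwich) standard errors. Written here because
# the marginal-model machinery is the inferential core of the repeated
# -visits analysis; with one observation per cluster the estimating
# equations reduce exactly to the GLM score, which the tests exploit as an
# independence-limit oracle.

#' Fit a marginal count regression by GEE
#'
#' Log-link mean model for counts with an offset, variance
#' `mu + mu^2 / theta` (Poisson when `theta = Inf`), exchangeable working
#' correlation within clusters, and robust sandwich variance for the
#' coefficients.
#'
#' @param formula model formula; the response must be a count. Use
#'   `offset()` inside the formula for the log-exposure.
#' @param data data frame holding the variables.
#' @param id cluster identifier (unquoted column name) in `data`.
#' @param theta NB2 dispersion; `Inf` gives the Poisson variance.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol convergence tolerance on the max absolute coefficient step.
#' @param maxit maximum number of Fisher-scoring iterations.
#' @return list of class `lifespacer_gee_engine`: `coefficients`,
#'   `vcov_robust`, `vcov_naive`, `alpha` (working correlation), `phi`
#'   (scale), `theta`, `n_clusters`, `n_obs`, `converged`, `iterations`.
#' @export
gee_count <- function(formula, data, id, theta = Inf,
                      corstr = c("exchangeable", "independence"),
                      tol = 1e-8, maxit = 200) {
  corstr <- match.arg(corstr)
  id <- data[[rlang::as_name(rlang::ensym(id))]]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  off <- stats::model.offset(mf) %||% rep(0, length(y))
  ord <- order(match(id, unique(id)))
  y <- y[ord]; X <- X[ord, , drop = FALSE]; off <- off[ord]; id <- id[ord]
  cluster_sizes <- table(factor(id, levels = unique(id)))
  starts <- cumsum(c(1, head(as.integer(cluster_sizes), -1)))
  ends <- cumsum(as.integer(cluster_sizes))
  n_clusters <- length(cluster_sizes)
  p <- ncol(X)
  if (corstr == "exchangeable" && all(cluster_sizes == 1)) {
    warn("no repeated observations within clusters; reducing to independence")
    corstr <- "independence"
  }
  beta <- suppressWarnings(
    coef(glm.fit(X, y, offset = off, family = poisson())))
  alpha <- 0; phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    v <- if (is.finite(theta)) mu + mu^2 / theta else mu
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      cross <- sum(vapply(seq_len(n_clusters), function(i) {
        ri <- r[starts[i]:ends[i]]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, numeric(1)))
      denom <- phi * (sum(cluster_sizes * (cluster_sizes - 1)) / 2 - p)
      alpha <- if (denom > 0) cross / denom else 0
      nmax <- max(cluster_sizes)
      alpha <- min(max(alpha, -1 / max(nmax - 1, 1) + 1e-6), 0.99)
    }
    H <- matrix(0, p, p)
    U <- numeric(p)
    score_list <- vector("list", n_clusters)
    for (i in seq_len(n_clusters)) {
      idx <- starts[i]:ends[i]
      ni <- length(idx)
      mui <- mu[idx]
      Di <- mui * X[idx, , drop = FALSE]
      a2i <- 1 / sqrt(v[idx])
      # exchangeable R^{-1} = (I - alpha J / (1 + (ni-1) alpha)) / (1-alpha)
      Z <- Di * a2i
      ei <- (y[idx] - mu[idx]) * a2i
      if (alpha != 0 && ni > 1) {
        shrink <- alpha / (1 + (ni - 1) * alpha)
        Gt <- (t(Z) - shrink * tcrossprod(colSums(Z), rep(1, ni))) /
          ((1 - alpha) * phi)
      } else {
        Gt <- t(Z) / phi
      }
      U <- U + drop(Gt %*% ei)
      H <- H + Gt %*% Z
      score_list[[i]] <- drop(Gt %*% ei)
    }
    delta <- solve(H, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)
  S <- do.call(rbind, score_list)
  M <- crossprod(S)
  Hinv <- solve(H)
  vcov_robust <- Hinv %*% M %*% Hinv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, vcov_robust = vcov_robust,
         vcov_naive = Hinv, alpha = alpha, phi = phi, theta = theta,
         n_clusters = n_clusters, n_obs = length(y),
         converged = converged, iterations = iter, corstr = corstr),
    class = "lifespacer_gee_engine")
}

#' GEE model of excursion parameters over repeated visits
#'
#' Marginal regression of an excursion outcome on fall status across the
#' baseline and year-1 visits, clustered by participant, with
#' exchangeable working correlation and robust SEs. The NB2 variance uses
#' the dispersion from a pooled maximum-likelihood NB fit. With
#' `visit_interaction = TRUE` a visit-number x fall-status term tests
#' whether the baseline-to-year-1 change differs by fall status; the
#' reported effect is then the interaction IRR.
#'
#' @inheritParams fit_excursion_nb
#' @param visit_interaction include and report the `exposure x visit`
#'   interaction?
#' @param corstr working correlation structure.
#' @return object of class `lifespacer_gee`; see [tidy.lifespacer_nb()].
#' @export
fit_excursion_gee <- function(rows, outcome = "daily_excursions",
                              exposure = "faller", adjusted = FALSE,
                              visit_interaction = FALSE,
                              corstr = "exchangeable") {
  rows <- check_rows(rows, outcome, exposure)
  rows[[exposure]] <- as.integer(rows[[exposure]])
  multi_visit <- dplyr::n_distinct(rows$visit) > 1
  terms <- c(exposure,
             if (multi_visit) "visit",
             if (visit_interaction) paste0(exposure, ":visit"),
             if (adjusted) ADJUSTMENT_COVARIATES)
  if (visit_interaction && !multi_visit) {
    abort("a visit interaction needs rows from both visits")
  }
  form <- as.formula(paste("total ~", paste(terms, collapse = " + "),
                           "+ offset(log_exposure)"))
  pooled <- suppressWarnings(
    MASS::glm.nb(form, data = rows,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 200)))
  engine <- gee_count(form, rows, participant_id, theta = pooled$theta,
                      corstr = corstr)
  term <- if (visit_interaction) paste0(exposure, ":visit") else exposure
  est <- engine$coefficients[[term]]
  se <- sqrt(engine$vcov_robust[term, term])
  z <- qnorm(0.975)
  result <- tibble::tibble(
    term = term, estimate = est, std.error = se, irr = exp(est),
    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    p_value = 2 * pnorm(-abs(est / se)))
  structure(
    list(engine = engine, result = result, outcome = outcome,
         exposure = exposure, model = "GEE",
         visit_interaction = visit_interaction,
         n_obs = engine$n_obs, n_clusters = engine$n_clusters,
         converged = engine$converged),
    class = "lifespacer_gee")
}

#' @export
print.lifespacer_gee <- function(x, ...) {
  cat(sprintf("<GEE%s> %s ~ %s (n = %d obs, %d participants)\n",
              if (x$visit_interaction) " visit-interaction" else "",
              x$outcome, x$exposure, x$n_obs, x$n_clusters))
  cat(sprintf("  %s: IRR %.2f (%.2f, %.2f), p = %.3g  [alpha = %.2f]\n",
              x$result$term, x$result$irr, x$result$ci_low,
              x$result$ci_high, x$result$p_value, x$engine$alpha))
  if (!x$converged) cat("  WARNING: did not converge\n")
  invisible(x)
}

#' @rdname tidy.lifespacer_nb
#' @export
tidy.lifespacer_gee <- function(x, exponentiate = TRUE, ...) {
  est <- unname(x$engine$coefficients)
  se <- unname(sqrt(diag(x$engine$vcov_robust)))
  z <- qnorm(0.975)
  out <- tibble::tibble(term = names(x$engine$coefficients),
                        estimate = est, std.error = se,
                        conf.low = est - z * se, conf.high = est + z * se,
                        p.value = 2 * pnorm(-abs(est / se)))
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(c("estimate", "conf.low",
                                              "conf.high"), exp))
  }
  out
}

#' @rdname tidy.lifespacer_nb
#' @export
glance.lifespacer_gee <- function(x, ...) {
  tibble::tibble(model = "GEE", outcome = x$outcome, exposure = x$exposure,
                 nobs = x$n_obs, n.clusters = x$n_clusters,
                 alpha = x$engine$alpha, phi = x$engine$phi,
                 theta = x$engine$theta, converged = x$converged)
}
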