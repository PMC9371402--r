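#' Gauss-Hermite quadrature for a standard-normal latent trait
#'
#' Nodes and weights for integrating against the N(0,1) ability prior,
#' obtained by the Golub-Welsch eigenvalue construction and transformed from
#' the physicists' Hermite weight. Weights are normalized to sum to one.
#'
#' @param n Number of quadrature points (default 21).
#' @return List with numeric vectors `nodes` and `weights`.
#' @export
normal_quadrature <- function(n = 21L) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  w <- e$vectors[1L, ord]^2
  list(nodes = e$values[ord] * sqrt(2), weights = w / sum(w))
}

#' Item characteristic curve
#'
#' Probability of a correct response under the three-parameter logistic
#' model, `P(theta) = c + (1 - c) / (1 + exp(-a (theta - b)))`. With `c = 0`
#' this is the 2PL curve; with `a = 1, c = 0` the Rasch curve.
#'
#' @param theta Latent ability (vectorized).
#' @param a Discrimination.
#' @param b Difficulty, on the same logit scale as `theta`.
#' @param c Guessing lower asymptote in `[0, 1)`.
#' @return Probabilities, same length as `theta`.
#' @examples
#' icc(0, a = 2.1448, b = 0.8017) # hardest item at average ability
#' @export
icc <- function(theta, a = 1, b = 0, c = 0) {
  c + (1 - c) * stats::plogis(a * (theta - b))
}

clamp_p <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

# item-by-node probability matrix (I x Q)
prob_matrix <- function(items, nodes) {
  P <- matrix(0, nrow(items), length(nodes))
  for (i in seq_len(nrow(items)))
    P[i, ] <- icc(nodes, items$a[i], items$b[i], items$c[i])
  clamp_p(P)
}

# per-respondent log-density at each node (N x Q) and marginal loglik
pattern_loglik <- function(X, P, weights) {
  M <- X %*% log(P) + (1 - X) %*% log(1 - P)   # N x Q via (N x I)(I x Q)
  M <- sweep(M, 2L, log(weights), `+`)
  mmax <- apply(M, 1L, max)
  ll_j <- mmax + log(rowSums(exp(M - mmax)))
  list(M = M, ll_j = ll_j, log_lik = sum(ll_j))
}

scores_of <- function(X) {
  if (inherits(X, "tol_response_matrix")) X$scores else as.matrix(X)
}

#' Fit a dichotomous IRT model by marginal maximum likelihood
#'
#' Rasch (difficulty only, discrimination fixed at 1), 2PL (difficulty and
#' discrimination) or 3PL (plus a guessing asymptote) estimated by an EM
#' algorithm: the E-step places posterior ability weight on Gauss-Hermite
#' nodes under the standard-normal prior, the M-step maximizes each item's
#' expected complete-data Bernoulli likelihood. The observed marginal
#' log-likelihood is non-decreasing across iterations and is tracked in
#' `ll_trace`. Standard errors come from the numerically differentiated
#' observed information at the optimum.
#'
#' @param X Binary respondent-by-item matrix (or a `tol_response_matrix`);
#'   column names are item ids.
#' @param model `"rasch"`, `"2pl"` or `"3pl"`.
#' @param n_quad Number of quadrature nodes (default 21).
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param se Compute standard errors (numerical observed information).
#'   Skipping them (`FALSE`) speeds up large simulation studies.
#' @return An object of class `tol_irt_fit`: `items` (per-item `a`, `b`,
#'   `c` and standard errors), `log_lik`, `ll_trace`, `n_params`, `n_obs`,
#'   `model`, `converged`, `iterations`, `flagged_items` (Heywood-type
#'   extreme estimates or all-constant items), and the quadrature `grid`.
#' @export
fit_irt <- function(X, model = c("2pl", "rasch", "3pl"), n_quad = 21L,
                    tol = 1e-6, max_iter = 500L, se = TRUE) {
  model <- match.arg(model)
  X <- scores_of(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(X %in% c(0, 1))) stop("matrix must be complete binary 0/1")
  N <- nrow(X); I <- ncol(X)
  if (I < 2L) stop("need at least 2 items")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("item_", seq_len(I))
  pbar <- colMeans(X)
  constant_items <- ids[pbar %in% c(0, 1)]
  if (length(constant_items))
    warning("all-constant items (no information): ",
            paste(constant_items, collapse = ", "))

  grid <- normal_quadrature(n_quad)
  th <- grid$nodes; wq <- grid$weights
  p0 <- clamp_p(pbar, 1 / (2 * N))
  items <- data.frame(item_id = ids,
                      a = if (model == "rasch") 1 else 1,
                      b = -stats::qlogis(p0),
                      c = 0, stringsAsFactors = FALSE)
  if (model == "3pl") items$c <- 0.001

  a_bounds <- c(0.05, 12); b_bounds <- c(-10, 10)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- prob_matrix(items, th)
    pl <- pattern_loglik(X, P, wq)
    ll <- pl$log_lik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    ll_old <- ll
    # E-step: posterior node weights per respondent
    post <- exp(pl$M - pl$ll_j)          # N x Q, rows sum to 1
    nq <- colSums(post)                  # expected respondents per node
    Rq <- crossprod(X, post)             # I x Q expected correct per node
    # M-step: independent weighted Bernoulli maximizations per item
    for (i in seq_len(I)) {
      r <- Rq[i, ]
      items[i, c("a", "b", "c")] <-
        mstep_item(r, nq, th, model,
                   unlist(items[i, c("a", "b", "c")]), a_bounds, b_bounds)
    }
  }

  flagged <- ids[items$a <= a_bounds[1] + 1e-6 | items$a >= a_bounds[2] - 1e-6 |
                 abs(items$b) >= 6]
  flagged <- union(flagged, constant_items)
  n_params <- I * switch(model, rasch = 1L, `2pl` = 2L, `3pl` = 3L)

  fit <- structure(list(
    model = model, items = items, log_lik = ll_trace[length(ll_trace)],
    ll_trace = ll_trace, n_params = n_params, n_obs = N, n_items = I,
    converged = converged, iterations = iter, grid = grid,
    flagged_items = flagged), class = "tol_irt_fit")
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations (delta ",
            signif(abs(fit$log_lik - ll_old), 3), ")")
  if (se) fit <- add_standard_errors(fit, X)
  fit
}

mstep_item <- function(r, nq, th, model, start, a_bounds, b_bounds) {
  if (model == "rasch") {
    nll <- function(b) {
      p <- clamp_p(stats::plogis(th - b))
      -sum(r * log(p) + (nq - r) * log(1 - p))
    }
    gr <- function(b) sum(r - nq * stats::plogis(th - b))
    o <- stats::optim(start[2], nll, gr, method = "L-BFGS-B",
                      lower = b_bounds[1], upper = b_bounds[2])
    c(1, o$par, 0)
  } else if (model == "2pl") {
    nll <- function(par) {
      p <- clamp_p(stats::plogis(par[1] * (th - par[2])))
      -sum(r * log(p) + (nq - r) * log(1 - p))
    }
    gr <- function(par) {
      p <- stats::plogis(par[1] * (th - par[2]))
      resid <- r - nq * p
      -c(sum(resid * (th - par[2])), -par[1] * sum(resid))
    }
    o <- stats::optim(start[1:2], nll, gr, method = "L-BFGS-B",
                      lower = c(a_bounds[1], b_bounds[1]),
                      upper = c(a_bounds[2], b_bounds[2]))
    c(o$par, 0)
  } else {
    # 3PL: guessing on a logit scale to keep c in (0, 0.5)
    nll <- function(par) {
      cc <- stats::plogis(par[3]) * 0.5
      p <- clamp_p(cc + (1 - cc) * stats::plogis(par[1] * (th - par[2])))
      -sum(r * log(p) + (nq - r) * log(1 - p))
    }
    st <- c(start[1], start[2], stats::qlogis(min(max(start[3] / 0.5, 1e-6), 1 - 1e-6)))
    o <- stats::optim(st, nll, method = "L-BFGS-B",
                      lower = c(a_bounds[1], b_bounds[1], -30),
                      upper = c(a_bounds[2], b_bounds[2], 0),
                      control = list(maxit = 200))
    c(o$par[1], o$par[2], stats::plogis(o$par[3]) * 0.5)
  }
}

free_params <- function(fit) {
  switch(fit$model,
         rasch = list(get = function(it) it$b,
                      set = function(it, v) { it$b <- v; it },
                      names = c("b")),
         `2pl` = list(get = function(it) c(it$a, it$b),
                      set = function(it, v) {
                        k <- length(v) / 2
                        it$a <- v[seq_len(k)]; it$b <- v[k + seq_len(k)]; it },
                      names = c("a", "b")),
         `3pl` = list(get = function(it) c(it$a, it$b, it$c),
                      set = function(it, v) {
                        k <- length(v) / 3
                        it$a <- v[seq_len(k)]; it$b <- v[k + seq_len(k)]
                        it$c <- v[2 * k + seq_len(k)]; it },
                      names = c("a", "b", "c")))
}

add_standard_errors <- function(fit, X) {
  fp <- free_params(fit)
  th <- fit$grid$nodes; wq <- fit$grid$weights
  ll_fun <- function(v) {
    it <- fp$set(fit$items, v)
    pattern_loglik(X, prob_matrix(it, th), wq)$log_lik
  }
  v0 <- fp$get(fit$items)
  k <- length(v0)
  h <- pmax(abs(v0), 1) * 1e-4
  H <- matrix(0, k, k)
  f0 <- ll_fun(v0)
  # central second differences of the marginal log-likelihood
  fp_ <- fm_ <- numeric(k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    fp_[i] <- ll_fun(v0 + e); fm_[i] <- ll_fun(v0 - e)
    H[i, i] <- (fp_[i] - 2 * f0 + fm_[i]) / h[i]^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ei <- numeric(k); ei[i] <- h[i]
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (ll_fun(v0 + ei + ej) - ll_fun(v0 + ei - ej) -
         ll_fun(v0 - ei + ej) + ll_fun(v0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  se <- rep(NA_real_, k)
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(cov)) {
    dg <- diag(cov)
    se[dg > 0] <- sqrt(dg[dg > 0])
    if (any(dg <= 0))
      warning("observed information not positive definite for some parameters")
  } else warning("observed information matrix is singular; SEs set to NA")
  I <- fit$n_items
  for (j in seq_along(fp$names))
    fit$items[[paste0("se_", fp$names[j])]] <- se[(j - 1) * I + seq_len(I)]
  fit
}

#' @export
print.tol_irt_fit <- function(x, ...) {
  cat(sprintf("<tol_irt_fit %s> %d items, N = %d\n", toupper(x$model),
              x$n_items, x$n_obs))
  cat(sprintf(" log-lik %.2f (k = %d), AIC %.2f, BIC %.2f; %d EM iterations%s\n",
              x$log_lik, x$n_params, aic(x), bic(x), x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$flagged_items))
    cat(" flagged items:", paste(x$flagged_items, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.tol_irt_fit <- function(object, ...) {
  structure(object$log_lik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Information criteria for an IRT fit
#'
#' `AIC = 2k - 2l` and `BIC = k log(N) - 2l` with `k` the free-parameter
#' count and `N` the number of respondents. The standard [stats::AIC()] and
#' [stats::BIC()] generics also work through the `logLik` method.
#'
#' @param fit A `tol_irt_fit`, or a bare log-likelihood value.
#' @param k,n Parameter count and sample size, only when `fit` is a bare
#'   log-likelihood.
#' @return Numeric scalar.
#' @examples
#' aic(-2333.38, k = 50)          # 4766.76
#' bic(-2333.38, k = 50, n = 214) # 4935.06
#' @export
aic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "tol_irt_fit")) return(2 * fit$n_params - 2 * fit$log_lik)
  2 * k - 2 * fit
}

#' @rdname aic
#' @export
bic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "tol_irt_fit"))
    return(fit$n_params * log(fit$n_obs) - 2 * fit$log_lik)
  k * log(n) - 2 * fit
}

#' Likelihood-ratio test between nested IRT fits
#'
#' @param fit_null The restricted model (e.g., Rasch).
#' @param fit_alt The nesting model (e.g., 2PL) fitted to the same matrix.
#' @return List with `statistic` (`2 (l_alt - l_null)`), `df`
#'   (free-parameter difference) and `p_value` (chi-square upper tail).
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "tol_irt_fit"), inherits(fit_alt, "tol_irt_fit"))
  order_of <- function(m) match(m, c("rasch", "2pl", "3pl"))
  if (order_of(fit_alt$model) <= order_of(fit_null$model))
    stop("models are not nested in the required order (null within alt)")
  if (fit_null$n_obs != fit_alt$n_obs || fit_null$n_items != fit_alt$n_items)
    stop("fits are not on the same response matrix")
  stat <- 2 * (fit_alt$log_lik - fit_null$log_lik)
  df <- fit_alt$n_params - fit_null$n_params
  list(statistic = stat, df = df,
       p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

#' Item and test information functions
#'
#' Fisher information about ability contributed by one item,
#' `a^2 ((P - c) / (1 - c))^2 (1 - P) / P` (reducing to `a^2 P (1 - P)` when
#' `c = 0`), and the test information as the sum over items.
#'
#' @param theta Ability values (vectorized).
#' @param a,b,c Item parameters.
#' @return Information values, same length as `theta`.
#' @export
item_information <- function(theta, a = 1, b = 0, c = 0) {
  P <- icc(theta, a, b, c)
  a^2 * ((P - c) / (1 - c))^2 * (1 - P) / P
}

#' @rdname item_information
#' @param fit A `tol_irt_fit`, or a data frame with columns `a`, `b` and
#'   optionally `c`.
#' @export
test_information <- function(theta, fit) {
  items <- if (inherits(fit, "tol_irt_fit")) fit$items else as.data.frame(fit)
  if (is.null(items$c)) items$c <- 0
  out <- numeric(length(theta))
  for (i in seq_len(nrow(items)))
    out <- out + item_information(theta, items$a[i], items$b[i], items$c[i])
  out
}

#' Expected a posteriori ability estimates
#'
#' Posterior mean and standard deviation of ability under the
#' standard-normal prior, computed on a quadrature grid.
#'
#' @param X Binary response matrix (respondents by items).
#' @param items Data frame with per-item `a`, `b`, `c` (columns beyond these
#'   are ignored), ordered as the matrix columns.
#' @param grid Quadrature grid from [normal_quadrature()]; a dense grid
#'   (default 61 nodes) keeps the quadrature error well below reporting
#'   precision.
#' @return Data frame with `theta` (posterior mean) and `theta_sd`.
#' @export
eap_ability <- function(X, items, grid = normal_quadrature(61L)) {
  X <- scores_of(X)
  storage.mode(X) <- "double"
  items <- as.data.frame(items)
  if (is.null(items$c)) items$c <- 0
  P <- prob_matrix(items, grid$nodes)
  pl <- pattern_loglik(X, P, grid$weights)
  post <- exp(pl$M - pl$ll_j)
  m <- drop(post %*% grid$nodes)
  v <- drop(post %*% grid$nodes^2) - m^2
  data.frame(theta = m, theta_sd = sqrt(pmax(v, 0)))
}

#' Chi-square item fit by ability groups
#'
#' For each item, respondents are grouped into deciles of the ability
#' estimate computed from the *other* items (the leave-one-out posterior
#' mean); within each group the observed proportion correct is compared
#' with the model-expected proportion (the posterior-predictive probability
#' under the same rest-only posterior), giving
#' `X^2 = sum_g N_g (O_g - E_g)^2 / (E_g (1 - E_g))` on `n_groups - 2`
#' degrees of freedom for the 2PL model. Conditioning both the grouping and
#' the expectation on the rest of the pattern keeps the statistic calibrated
#' under the null (grouping on a score that contains the item itself
#' inflates it badly). Groups left empty by ties are merged with a warning.
#'
#' @param fit A `tol_irt_fit`.
#' @param X The response matrix the model was fitted to.
#' @param n_groups Number of ability groups (default 10).
#' @return Data frame with `item_id`, `chisq`, `df`, `p_value`.
#' @export
item_fit_chisq <- function(fit, X, n_groups = 10L) {
  X <- scores_of(X)
  storage.mode(X) <- "double"
  th <- fit$grid$nodes; wq <- fit$grid$weights
  P <- prob_matrix(fit$items, th)
  M <- X %*% log(P) + (1 - X) %*% log(1 - P)
  M <- sweep(M, 2L, log(wq), `+`)
  npar_item <- switch(fit$model, rasch = 1L, `2pl` = 2L, `3pl` = 3L)
  out <- data.frame(item_id = fit$items$item_id,
                    chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  merged <- FALSE
  for (i in seq_len(fit$n_items)) {
    # posterior given the rest of the response pattern (item i removed)
    Mi <- M - (X[, i, drop = FALSE] %*% log(P[i, , drop = FALSE]) +
               (1 - X[, i, drop = FALSE]) %*% log(1 - P[i, , drop = FALSE]))
    mmax <- apply(Mi, 1L, max)
    ll_j <- mmax + log(rowSums(exp(Mi - mmax)))
    post <- exp(Mi - ll_j)
    eap_loo <- drop(post %*% th)
    e_j <- drop(post %*% P[i, ])          # posterior-predictive P(correct)
    br <- unique(stats::quantile(eap_loo,
                                 probs = seq(0, 1, length.out = n_groups + 1L)))
    if (length(br) < n_groups + 1L) merged <- TRUE
    grp <- cut(eap_loo, breaks = br, include.lowest = TRUE, labels = FALSE)
    ng <- length(br) - 1L
    chisq <- 0
    for (g in seq_len(ng)) {
      sel <- grp == g
      Ng <- sum(sel)
      Og <- mean(X[sel, i])
      Eg <- clamp_p(mean(e_j[sel]), 1e-8)
      chisq <- chisq + Ng * (Og - Eg)^2 / (Eg * (1 - Eg))
    }
    df <- ng - npar_item
    out$chisq[i] <- chisq
    out$df[i] <- df
    out$p_value[i] <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  if (merged) warning("tied ability estimates: some groups merged")
  out
}
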