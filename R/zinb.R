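# Zero-inflated negative binomial generalized linear mixed model.
#
# Count part: y ~ NB2(mu, theta) with log mu = x'beta + log N + u_g, where N
# is head slaughtered (offset) and u_g ~ Normal(0, sigma_u^2) is a random
# intercept for the five-level processing-volume category. Zero part: an
# intercept-only structural-zero probability pi (no covariates, no random
# effect). The marginal likelihood integrates u out per group by adaptive
# Gauss-Hermite quadrature (Laplace when quad_points = 1) and is maximized
# by quasi-Newton on the transformed scale (beta, log theta, logit pi,
# log sigma_u).

#' Zero-inflated negative binomial probability mass function
#'
#' NB2 parameterization: `Var(Y) = mu + mu^2 / theta`. The zero mass is
#' `pi + (1 - pi) * (theta / (theta + mu))^theta`; positive counts carry
#' `(1 - pi)` times the negative binomial mass.
#'
#' @param y non-negative integer counts.
#' @param mu positive means.
#' @param theta positive dispersion.
#' @param pi structural-zero probability in \[0, 1).
#' @param log return the log probability.
#' @return probabilities (or log probabilities).
#' @examples
#' dzinb(0, mu = 1, theta = 1, pi = 0.2)  # 0.6
#' @export
dzinb <- function(y, mu, theta, pi = 0, log = FALSE) {
  if (any(y < 0) || any(y != floor(y)))
    abort_domain("y must be non-negative integers")
  if (any(mu <= 0) || theta <= 0 || pi < 0 || pi >= 1)
    abort_domain("require mu > 0, theta > 0, and pi in [0, 1)")
  n <- max(length(y), length(mu))
  y <- rep_len(as.numeric(y), n)
  mu <- rep_len(as.numeric(mu), n)
  lp <- .zinb_logpmf_cpp(y, mu, theta, pi)
  if (log) lp else exp(lp)
}

#' Draw from the zero-inflated negative binomial
#' @param n number of draws.
#' @inheritParams dzinb
#' @return integer vector of counts.
#' @export
rzinb <- function(n, mu, theta, pi = 0) {
  structural <- rbinom(n, 1L, pi) == 1L
  y <- rnbinom(n, mu = rep_len(mu, n), size = theta)
  y[structural] <- 0L
  y
}

# Nested fixed-effect design: one indicator per class (each class's own
# baseline) plus one per class x non-baseline category, so the log risk
# ratio against the class baseline is a single coefficient.
build_design <- function(class, category = NULL, baseline = "baseline") {
  class <- as.character(class)
  classes <- sort(unique(class))
  cols <- list()
  info <- list()
  for (cl in classes) {
    cols[[length(cols) + 1L]] <- as.numeric(class == cl)
    info[[length(info) + 1L]] <-
      tibble(term = cl, class = cl, category = baseline)
  }
  if (!is.null(category)) {
    category <- as.character(category)
    for (cl in classes) {
      cats <- sort(setdiff(unique(category[class == cl]), baseline))
      for (ct in cats) {
        cols[[length(cols) + 1L]] <- as.numeric(class == cl & category == ct)
        info[[length(info) + 1L]] <-
          tibble(term = paste0(cl, ":", ct), class = cl, category = ct)
      }
    }
  }
  X <- do.call(cbind, cols)
  info <- bind_rows(info)
  colnames(X) <- info$term
  aliased <- colSums(X) == 0
  if (any(aliased))
    abort_domain("aliased design columns: ",
                 paste(info$term[aliased], collapse = ", "))
  if (qr(X)$rank < ncol(X))
    abort_domain("design matrix is rank deficient")
  list(X = X, info = info, baseline = baseline)
}

gh_rule <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))  # Laplace approximation
  r <- pracma::gaussHermite(n)
  list(x = r$x, w = r$w)
}

# marginal log-likelihood at a parameter list, via the C++ kernel
zinb_marginal_ll <- function(beta, theta, pi, sigma, y, X, offset, group_idx,
                             n_groups, gh, u_start = rep(0, n_groups)) {
  .zinb_marginal_cpp(beta, theta, pi, sigma, y, X, offset,
                     as.integer(group_idx), n_groups, gh$x, gh$w,
                     u_start)$loglik
}

#' Fit the zero-inflated negative binomial mixed model
#'
#' Maximizes the marginal likelihood directly: for each random-effect group
#' the integral over the Gaussian random intercept is evaluated by adaptive
#' Gauss-Hermite quadrature centred at the group mode (Laplace approximation
#' when `quad_points = 1`). Standard errors come from the numerical Hessian
#' at the optimum (Wald).
#'
#' @param data data frame of weekly records with the response, head counts,
#'   grouping, and the fixed-effect columns.
#' @param response,total,group column names for the condemned count, the
#'   head slaughtered (offset is `log(total)`), and the random-effect
#'   grouping (processing-volume category).
#' @param class_col column of swine class; always in the fixed design.
#' @param category_col optional column of exposure category; when supplied,
#'   categories are nested within class (each class's `baseline_category` is
#'   its own reference).
#' @param baseline_category reference category label (default `"baseline"`).
#' @param quad_points number of quadrature nodes (default 15; 1 = Laplace).
#' @param zero_inflation estimate the structural-zero probability (`TRUE`) or
#'   fix `pi = 0`.
#' @param random_effect estimate the random-intercept SD (`TRUE`) or fix
#'   `sigma_u = 0`.
#' @param control passed to [stats::optim()] (method BFGS).
#' @return a `zinb_fit` object: `beta`, `se_beta`, `vcov_beta`, `theta`,
#'   `pi`, `sigma_u`, `u_hat` (per-group modes), `loglik`, `converged`,
#'   `design` (term metadata), and the model frame pieces needed for
#'   prediction.
#' @export
fit_zinb_glmm <- function(data, response = "condemned", total = "total",
                          group = "volume_category", class_col = "class",
                          category_col = NULL, baseline_category = "baseline",
                          quad_points = 15, zero_inflation = TRUE,
                          random_effect = TRUE, control = list()) {
  y <- data[[response]]
  N <- data[[total]]
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    abort_domain("response must be non-negative integer counts")
  if (any(N < 1)) abort_domain("total head must be >= 1 on every row")
  # a class x category cell with no condemnations at all has no finite rate
  # MLE (the coefficient diverges); such strata are dropped with a warning,
  # as an analyst would exclude a zero-event stratum
  dropped_cells <- character()
  if (!is.null(category_col)) {
    cell <- paste(data[[class_col]], data[[category_col]])
    ev <- tapply(y, cell, sum)
    bad <- names(ev)[ev == 0]
    if (length(bad) > 0) {
      warning("dropping zero-event cell(s): ", paste(bad, collapse = ", "),
              call. = FALSE)
      keep <- !cell %in% bad
      data <- data[keep, , drop = FALSE]
      y <- y[keep]; N <- N[keep]
      dropped_cells <- bad
    }
  }
  g <- factor(data[[group]])
  if (random_effect && nlevels(g) < 2)
    abort_domain("need at least 2 random-effect groups")
  des <- build_design(data[[class_col]],
                      if (!is.null(category_col)) data[[category_col]],
                      baseline_category)
  X <- des$X
  offset <- log(N)
  group_idx <- as.integer(g) - 1L
  n_groups <- nlevels(g)
  gh <- gh_rule(quad_points)
  p <- ncol(X)

  # starting values: Poisson fit for beta, method-of-moments theta,
  # observed zero excess for pi, modest sigma
  pois <- glm.fit(X, y, offset = offset, family = poisson())
  beta0 <- coef(pois)
  mu0 <- exp(drop(X %*% beta0) + offset)
  disp <- sum((y - mu0)^2 / mu0^2, na.rm = TRUE) / length(y)
  theta0 <- min(max(1 / max(disp - mean(1 / mu0), 0.05), 0.05), 50)
  pi0 <- min(max(mean(y == 0) / 2, 0.02), 0.8)
  sigma0 <- 0.2

  pack <- function(beta, theta, pi, sigma) {
    c(beta, log(theta),
      if (zero_inflation) qlogis(pi),
      if (random_effect) log(sigma))
  }
  unpack <- function(par) {
    par <- unname(par)
    i <- p
    theta <- exp(par[i + 1L]); i <- i + 1L
    pi <- if (zero_inflation) { i <- i + 1L; plogis(par[i]) } else 0
    sigma <- if (random_effect) exp(par[i + 1L]) else 0
    list(beta = par[seq_len(p)], theta = theta, pi = pi, sigma = sigma)
  }
  # warm-started group modes: the inner Newton search restarts from the
  # modes of the previous likelihood call, which is nearby during the
  # optimizer's path
  warm <- new.env(parent = emptyenv())
  warm$u <- rep(0, n_groups)
  nll <- function(par) {
    q <- unpack(par)
    if (!all(is.finite(par)) || q$theta > 1e7 || q$sigma > 50) return(1e10)
    res <- .zinb_marginal_cpp(q$beta, q$theta, q$pi, q$sigma, y, X, offset,
                              as.integer(group_idx), n_groups, gh$x, gh$w,
                              warm$u)
    if (!is.finite(res$loglik)) return(1e10)
    warm$u <- drop(res$u_hat)
    -res$loglik
  }
  grad <- function(par) {
    # forward differences with a shared base evaluation: p + 1 likelihood
    # calls per gradient instead of 2p
    f0 <- nll(par)
    vapply(seq_along(par), function(j) {
      h <- 1e-6 * (1 + abs(par[j]))
      e <- rep(0, length(par)); e[j] <- h
      (nll(par + e) - f0) / h
    }, numeric(1))
  }
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-11), control)

  run_optim <- function(par0) {
    optim(par0, nll, gr = grad, method = "BFGS", control = ctrl)
  }
  par0 <- pack(beta0, theta0, pi0, sigma0)
  opt <- run_optim(par0)
  if (opt$convergence != 0) {
    # deterministic random restarts around the best point so far
    for (r in 1:3) {
      set.seed(1000L + r)
      jit <- rnorm(length(par0), 0, 0.2)
      try({
        alt <- run_optim(opt$par + jit)
        if (alt$value < opt$value) opt <- alt
      }, silent = TRUE)
      if (opt$convergence == 0) break
    }
  }
  q <- unpack(opt$par)
  full <- .zinb_marginal_cpp(q$beta, q$theta, q$pi, q$sigma, y, X, offset,
                             group_idx, n_groups, gh$x, gh$w, warm$u)
  hess_fd <- function(par) {
    # forward differences of the gradient; (p+1)^2 likelihood calls
    g0 <- grad(par)
    H <- matrix(0, length(par), length(par))
    for (j in seq_along(par)) {
      h <- 1e-4 * (1 + abs(par[j]))
      e <- rep(0, length(par)); e[j] <- h
      H[, j] <- (grad(par + e) - g0) / h
    }
    (H + t(H)) / 2
  }
  H <- try(hess_fd(opt$par), silent = TRUE)
  vcov_all <- if (inherits(H, "try-error")) NULL else
    tryCatch(solve(H), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(vcov_all) &&
    all(is.finite(diag(vcov_all)[seq_len(p)])) &&
    all(diag(vcov_all)[seq_len(p)] > 0)
  vcov_beta <- if (!is.null(vcov_all)) {
    vb <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
    (vb + t(vb)) / 2
  } else {
    matrix(NA_real_, p, p)
  }
  dimnames(vcov_beta) <- list(des$info$term, des$info$term)
  beta <- setNames(q$beta, des$info$term)

  structure(list(
    beta = beta,
    se_beta = sqrt(pmax(diag(vcov_beta), 0)),
    vcov_beta = vcov_beta,
    theta = q$theta, pi = q$pi, sigma_u = q$sigma,
    u_hat = setNames(full$u_hat, levels(g)),
    loglik = full$loglik,
    converged = converged,
    diagnostics = list(optim_convergence = opt$convergence,
                       message = opt$message, counts = opt$counts,
                       n = length(y)),
    design = des$info, dropped_cells = dropped_cells,
    baseline_category = baseline_category,
    quad_points = quad_points,
    zero_inflation = zero_inflation, random_effect = random_effect,
    frame = list(y = y, X = X, offset = offset, group_idx = group_idx,
                 n_groups = n_groups, group_levels = levels(g))
  ), class = "zinb_fit")
}

#' Recompute the marginal log-likelihood of a fit
#'
#' Useful for quadrature self-consistency checks: the value should be stable
#' in `quad_points` once the rule is fine enough.
#'
#' @param fit a `zinb_fit`.
#' @param quad_points quadrature nodes (default: as fitted).
#' @return marginal log-likelihood (numeric scalar).
#' @export
zinb_loglik <- function(fit, quad_points = fit$quad_points) {
  gh <- gh_rule(quad_points)
  f <- fit$frame
  zinb_marginal_ll(unname(fit$beta), fit$theta, fit$pi, fit$sigma_u,
                   f$y, f$X, f$offset, f$group_idx, f$n_groups, gh)
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated negative binomial mixed model\n")
  cat(sprintf("  n = %d rows, %d groups; logLik = %.3f; %s\n",
              x$diagnostics$n, x$frame$n_groups, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  theta = %.4f  pi = %.4f  sigma_u = %.4f\n",
              x$theta, x$pi, x$sigma_u))
  est <- cbind(estimate = x$beta, se = x$se_beta)
  print(round(est, 4))
  invisible(x)
}

#' Population-level condemnation rate (CR) per head
#'
#' `CR = (1 - pi) * exp(x'beta)` at the population level: the random
#' intercept is set to zero and the offset contribution removed, so the rate
#' is per head slaughtered. This is the "estimated probability condemned"
#' under the per-head Poisson-thinning approximation (rates here are a few
#' per thousand, where mean-per-head and probability coincide to first
#' order).
#'
#' @param fit a converged `zinb_fit`.
#' @param class,category vectors (recycled) naming design cells.
#' @return numeric vector of per-head rates.
#' @export
predict_rate <- function(fit, class, category = fit$baseline_category) {
  stopifnot(inherits(fit, "zinb_fit"))
  if (!fit$converged) abort_domain("fit did not converge; rates unavailable")
  n <- max(length(class), length(category))
  class <- rep_len(as.character(class), n)
  category <- rep_len(as.character(category), n)
  vapply(seq_len(n), function(i) {
    lr <- log_rate_terms(fit, class[i], category[i])
    (1 - fit$pi) * exp(sum(fit$beta[lr]))
  }, numeric(1))
}

# terms contributing to the log rate of one (class, category) cell
log_rate_terms <- function(fit, class, category) {
  d <- fit$design
  if (!class %in% d$class)
    abort_domain("unknown class: ", class)
  base <- d$term[d$class == class & d$category == fit$baseline_category]
  if (category == fit$baseline_category) return(base)
  term <- d$term[d$class == class & d$category == category]
  if (length(term) == 0)
    abort_domain("category '", category, "' not in the design for class '",
                 class, "'")
  c(base, term)
}

#' Predicted condemnation counts for new records
#'
#' Expected counts `(1 - pi) * exp(x'beta + log N + u_g)`. With
#' `prediction = "conditional"` (default) the estimated random-effect mode
#' of the record's group is included — the prediction for the observed
#' plants; `"population"` sets `u = 0`.
#'
#' @param object a converged `zinb_fit`.
#' @param newdata data frame with the class (and category, if the fit used
#'   one), `total`, and the grouping column.
#' @param prediction `"conditional"` or `"population"`.
#' @param total,group,class_col,category_col column names, as in
#'   [fit_zinb_glmm()].
#' @param ... unused.
#' @return numeric vector of expected counts.
#' @export
predict.zinb_fit <- function(object, newdata,
                             prediction = c("conditional", "population"),
                             total = "total", group = "volume_category",
                             class_col = "class", category_col = NULL,
                             ...) {
  prediction <- match.arg(prediction)
  fit <- object
  if (!fit$converged) abort_domain("fit did not converge")
  cls <- as.character(newdata[[class_col]])
  cat <- if (is.null(category_col)) rep(fit$baseline_category, nrow(newdata))
         else as.character(newdata[[category_col]])
  log_rate <- vapply(seq_len(nrow(newdata)), function(i)
    sum(fit$beta[log_rate_terms(fit, cls[i], cat[i])]), numeric(1))
  u <- if (prediction == "conditional") {
    gl <- as.character(newdata[[group]])
    miss <- setdiff(unique(gl), names(fit$u_hat))
    if (length(miss) > 0)
      abort_domain("records lack a fitted volume category: ",
                   paste(miss, collapse = ", "))
    unname(fit$u_hat[gl])
  } else 0
  (1 - fit$pi) * exp(log_rate + log(newdata[[total]]) + u)
}

#' Serialize a fit to JSON and a text report
#'
#' @param fit a `zinb_fit`.
#' @param json_path,txt_path output paths (either may be `NULL`).
#' @return the report list, invisibly.
#' @export
write_fit_report <- function(fit, json_path = NULL, txt_path = NULL) {
  rep <- list(
    coefficients = as.list(fit$beta),
    se = as.list(setNames(fit$se_beta, names(fit$beta))),
    theta = fit$theta, pi = fit$pi, sigma_u = fit$sigma_u,
    u_hat = as.list(fit$u_hat),
    loglik = fit$loglik, converged = fit$converged,
    n = fit$diagnostics$n, quad_points = fit$quad_points
  )
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(fit); sink()
    close(con)
  }
  invisible(rep)
}
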