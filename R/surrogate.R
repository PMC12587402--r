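# Matern 5/2 correlation matrix between scaled inputs.
# X1, X2: n x d matrices already divided by the length scales.
matern52 <- function(X1, X2) {
  # squared scaled distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  r <- sqrt(pmax(d2, 0))
  s5r <- sqrt(5) * r
  (1 + s5r + 5 * r^2 / 3) * exp(-s5r)
}

# Negative log marginal likelihood of the standardized-target GP, with its
# analytic gradient. theta = c(log lengthscales (d), log output sd,
# log noise sd). Per-dimension squared-distance matrices are precomputed
# once per training set; fn/gr share one cached kernel factorization, which
# makes the multi-restart MLE cheap enough to rerun at every
# Kriging-believer refit.
make_gp_objective <- function(X, y) {
  n <- nrow(X)
  d <- ncol(X)
  D2 <- lapply(seq_len(d), function(j) outer(X[, j], X[, j], `-`)^2)
  cache <- new.env(parent = emptyenv())
  compute <- function(theta) {
    if (identical(cache$theta, theta)) return(invisible())
    ls2 <- exp(2 * theta[1:d])
    s2 <- exp(2 * theta[d + 1])
    n2 <- exp(2 * theta[d + 2])
    r2 <- 0
    for (j in seq_len(d)) r2 <- r2 + D2[[j]] / ls2[j]
    r <- sqrt(pmax(r2, 0))
    E <- exp(-sqrt(5) * r)
    M <- (1 + sqrt(5) * r + 5 * r2 / 3) * E
    K <- s2 * M
    diag(K) <- diag(K) + n2 + 1e-10
    L <- tryCatch(chol(K), error = function(e) NULL)
    cache$theta <- theta
    if (is.null(L)) {
      cache$bad <- TRUE
      return(invisible())
    }
    cache$bad <- FALSE
    alpha <- backsolve(L, forwardsolve(t(L), y))
    cache$nll <- as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
                              0.5 * n * log(2 * pi))
    cache$W <- chol2inv(L) - tcrossprod(alpha)   # K^-1 - alpha alpha^T
    cache$G <- (5 / 3) * (1 + sqrt(5) * r) * E   # dM / d(scaled sq dist)
    cache$M <- M
    cache$ls2 <- ls2; cache$s2 <- s2; cache$n2 <- n2
    invisible()
  }
  list(
    fn = function(theta) {
      compute(theta)
      if (cache$bad) 1e10 else cache$nll
    },
    gr = function(theta) {
      compute(theta)
      if (cache$bad) return(numeric(d + 2L))
      g <- numeric(d + 2L)
      for (j in seq_len(d)) {
        g[j] <- 0.5 * sum(cache$W * (cache$s2 * cache$G *
                                       (D2[[j]] / cache$ls2[j])))
      }
      g[d + 1L] <- sum(cache$W * (cache$s2 * cache$M))
      g[d + 2L] <- cache$n2 * sum(diag(cache$W))
      g
    }
  )
}

#' Fit a Gaussian-process surrogate for one objective
#'
#' An independent GP regression with a Matern 5/2 kernel and per-dimension
#' length scales, fitted on normalized (unit-cube) inputs. Targets are
#' standardized to zero mean and unit variance internally; predictions are
#' returned in raw objective units. Hyperparameters (length scales, output
#' variance and a jointly learned noise variance) maximize the log marginal
#' likelihood via multi-restart L-BFGS-B on the log scale.
#'
#' @param X Training inputs: matrix or data frame, rows in `[0, 1]^d`.
#' @param y Raw objective values, one per row of `X`.
#' @param objective Objective name, carried into reports.
#' @param restarts Number of optimizer restarts; the first starts from a
#'   mid-range default, the rest from log-uniform draws within the bounds
#'   (consumes the R random number stream).
#' @param lengthscale_bounds Bounds for each length scale on the unit cube.
#' @param noise_bounds Bounds for the noise standard deviation (standardized
#'   scale); the lower bound is the noise-variance floor.
#' @param fixed Optional named list to bypass MLE: `lengthscales`,
#'   `output_sd`, `noise_sd` (standardized scale). Used for diagnostics and
#'   cross-checks.
#' @return An object of class `formubo_gp`.
#' @examples
#' X <- matrix(runif(20 * 6), 20)
#' fit <- fit_objective_model(X, rowSums(X), objective = "toy", restarts = 2)
#' predict(fit, matrix(0.5, 1, 6))
#' @export
fit_objective_model <- function(X, y, objective = "objective", restarts = 10,
                                lengthscale_bounds = c(1e-2, 1e2),
                                noise_bounds = c(1e-4, 10),
                                fixed = NULL) {
  X <- as.matrix(as.data.frame(X))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("|X| must equal |y|",
                                  class = "formubo_config_error")
  if (length(y) < 2L) abort("need at least 2 observations to fit a GP",
                            class = "formubo_config_error")
  d <- ncol(X)
  ym <- mean(y)
  ys <- sd(y)
  if (!is.finite(ys) || ys < 1e-8) {
    warn(paste0("objective '", objective,
                "' has (near-)zero variance; using floor sd"))
    ys <- 1e-8
  }
  yst <- (y - ym) / ys

  obj <- make_gp_objective(X, yst)
  if (!is.null(fixed)) {
    theta <- c(log(rep_len(fixed$lengthscales, d)),
               log(fixed$output_sd %||% 1),
               log(fixed$noise_sd %||% noise_bounds[1]))
    nll <- obj$fn(theta)
  } else {
    lb <- c(rep(log(lengthscale_bounds[1]), d), log(1e-3),
            log(noise_bounds[1]))
    ub <- c(rep(log(lengthscale_bounds[2]), d), log(1e3),
            log(noise_bounds[2]))
    starts <- vector("list", max(restarts, 1L))
    starts[[1]] <- c(rep(log(0.5), d), log(1), log(0.1))
    if (restarts > 1L) {
      for (i in 2:restarts) {
        starts[[i]] <- runif(d + 2L, lb, ub)
      }
    }
    fits <- lapply(starts, function(s) {
      tryCatch(
        optim(s, obj$fn, obj$gr, method = "L-BFGS-B",
              lower = lb, upper = ub, control = list(maxit = 200)),
        error = function(e) list(par = s, value = obj$fn(s))
      )
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    theta <- best$par
    nll <- best$value
  }

  ls <- exp(theta[1:d])
  s2 <- exp(2 * theta[d + 1])
  n2 <- exp(2 * theta[d + 2])
  Xs <- sweep(X, 2L, ls, `/`)
  K <- s2 * matern52(Xs, Xs) + diag(n2 + 1e-10, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yst))

  structure(
    list(objective = objective, X = X, y = y, y_mean = ym, y_sd = ys,
         lengthscales = ls, output_var = s2, noise_var = n2,
         L = L, alpha = alpha, log_lik = -nll,
         control = list(restarts = restarts,
                        lengthscale_bounds = lengthscale_bounds,
                        noise_bounds = noise_bounds, fixed = fixed)),
    class = "formubo_gp"
  )
}

#' Posterior mean and standard deviation of a fitted surrogate
#'
#' @param object A fitted `formubo_gp`.
#' @param newdata Points to predict at: matrix or data frame with the same
#'   number of columns as the training inputs.
#' @param ... Unused.
#' @return A tibble with columns `.mean` and `.sd`, in raw objective units.
#'   The `.sd` is the posterior sd of the latent function (no observation
#'   noise added), so it shrinks to ~0 at training points of a near-noiseless
#'   fit and reverts to the prior scale far from all data.
#' @export
predict.formubo_gp <- function(object, newdata, ...) {
  Xn <- as.matrix(as.data.frame(newdata))
  if (ncol(Xn) != ncol(object$X)) {
    abort("newdata dimension mismatch", class = "formubo_config_error")
  }
  Xs <- sweep(object$X, 2L, object$lengthscales, `/`)
  Xns <- sweep(Xn, 2L, object$lengthscales, `/`)
  Kx <- object$output_var * matern52(Xns, Xs)       # m x n
  mu <- drop(Kx %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Kx))             # n x m
  var_post <- pmax(object$output_var - colSums(v^2), 0)
  tibble::tibble(.mean = object$y_mean + object$y_sd * mu,
                 .sd = object$y_sd * sqrt(var_post))
}

#' @rdname predict.formubo_gp
#' @param model A fitted `formubo_gp`.
#' @param X Points to predict at.
#' @export
predict_mean_sd <- function(model, X) {
  if (!inherits(model, "formubo_gp")) {
    abort("model must be a fitted formubo_gp", class = "formubo_config_error")
  }
  predict(model, X)
}

#' Kriging-believer fantasy augmentation
#'
#' Appends the model's own posterior mean at `x` to the training set as if it
#' had been observed, then refits the hyperparameters. Used by the greedy
#' batch-acquisition loop so that later picks in a batch account for earlier
#' ones.
#'
#' @param model A fitted `formubo_gp`.
#' @param x A single point in the unit cube.
#' @return A refitted `formubo_gp` with one extra training row.
#' @export
augment_with_fantasy <- function(model, x) {
  x <- matrix(as.numeric(x), nrow = 1L)
  fantasy <- predict(model, x)$.mean
  fit_objective_model(
    rbind(model$X, x), c(model$y, fantasy), objective = model$objective,
    restarts = model$control$restarts,
    lengthscale_bounds = model$control$lengthscale_bounds,
    noise_bounds = model$control$noise_bounds,
    fixed = model$control$fixed
  )
}

#' @export
print.formubo_gp <- function(x, ...) {
  cat(sprintf("<formubo GP surrogate: %s>\n", x$objective))
  cat(sprintf("  n = %d, d = %d, logLik = %.3f\n", nrow(x$X), ncol(x$X),
              x$log_lik))
  cat("  lengthscales:", paste(signif(x$lengthscales, 3), collapse = " "),
      "\n")
  cat(sprintf("  output sd %.3g, noise sd %.3g (standardized scale)\n",
              sqrt(x$output_var), sqrt(x$noise_var)))
  invisible(x)
}

#' @method tidy formubo_gp
#' @export
tidy.formubo_gp <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("lengthscale_", seq_along(x$lengthscales)),
             "output_sd", "noise_sd"),
    estimate = c(x$lengthscales, sqrt(x$output_var), sqrt(x$noise_var))
  )
}

#' @method glance formubo_gp
#' @export
glance.formubo_gp <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, nobs = nrow(x$X), logLik = x$log_lik,
    y_mean = x$y_mean, y_sd = x$y_sd, noise_sd = sqrt(x$noise_var)
  )
}

# Serialize a GP to a plain list (for YAML/JSON persistence) and back.
gp_to_record <- function(model) {
  list(objective = model$objective,
       X = apply(model$X, 1L, as.numeric, simplify = FALSE),
       y = as.numeric(model$y),
       lengthscales = as.numeric(model$lengthscales),
       output_var = model$output_var, noise_var = model$noise_var,
       control = model$control[c("restarts", "lengthscale_bounds",
                                 "noise_bounds")])
}

gp_from_record <- function(rec) {
  X <- do.call(rbind, lapply(rec$X, as.numeric))
  fit_objective_model(
    X, rec$y, objective = rec$objective,
    restarts = rec$control$restarts,
    lengthscale_bounds = rec$control$lengthscale_bounds,
    noise_bounds = rec$control$noise_bounds,
    fixed = list(lengthscales = rec$lengthscales,
                 output_sd = sqrt(rec$output_var),
                 noise_sd = sqrt(rec$noise_var))
  )
}
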