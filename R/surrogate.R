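# ---- Exact Gaussian-process regression (RBF + noise kernel) -----------

gp_kernel <- function(D2, ls, s2) s2 * exp(-0.5 * D2 / ls^2)

gp_neg_loglik <- function(theta, D2, y) {
  ls <- exp(theta[1]); s2 <- exp(theta[2]); n2 <- exp(theta[3])
  n <- length(y)
  K <- gp_kernel(D2, ls, s2) + diag(n2 + 1e-10, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(ch))) +
               0.5 * n * log(2 * pi))
}

#' Fit an exact Gaussian process (radial-basis + noise kernel)
#'
#' Zero-mean GP regression with an isotropic squared-exponential kernel
#' plus independent noise. Hyperparameters (lengthscale, signal variance,
#' noise variance) are optimized by maximum marginal likelihood from a
#' small deterministic grid of restarts.
#'
#' @param X Numeric feature matrix (rows = points).
#' @param y Numeric targets.
#' @return Object of class `gp_fit` with predict method.
#' @export
gp_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  med <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) med <- 1
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6
  starts <- rbind(
    c(0.5 * log(med), log(vy), log(vy * 0.1 + 1e-8)),
    c(0.5 * log(med) + 1, log(vy), log(vy * 0.01 + 1e-8)),
    c(0.5 * log(med) - 1, log(vy), log(vy * 0.5 + 1e-8)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- tryCatch(stats::optim(starts[s, ], gp_neg_loglik, D2 = D2, y = y,
                               method = "L-BFGS-B",
                               lower = starts[s, ] - 8, upper = starts[s, ] + 8),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) best <- list(par = starts[1, ], value = NA_real_)
  ls <- exp(best$par[1]); s2 <- exp(best$par[2]); n2 <- exp(best$par[3])
  K <- gp_kernel(D2, ls, s2) + diag(n2 + 1e-10, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  structure(list(X = X, y = y, ls = ls, s2 = s2, n2 = n2,
                 chol = ch, alpha = alpha, nll = best$value),
            class = "gp_fit")
}

#' @export
predict.gp_fit <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  # squared distances between new and training points
  d2 <- outer(rowSums(Xs^2), rowSums(object$X^2), "+") -
    2 * tcrossprod(Xs, object$X)
  d2[d2 < 0] <- 0
  Ks <- gp_kernel(d2, object$ls, object$s2)
  mu <- as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(Ks))
  var <- pmax(object$s2 + object$n2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var))
}

# ---- Two-stage surrogate ----------------------------------------------

#' Train the two-stage surrogate (random forest + GP on residuals)
#'
#' Stage 1 is a random-forest regression of the normalized half-time on
#' the molecular features; stage 2 is a Gaussian process fitted to the
#' in-sample residuals of the forest. Predictions are RF mean plus GP
#' residual mean; predictive uncertainty is the GP's predictive SD.
#'
#' @param features Numeric matrix (molecules x features), rownames = ids.
#' @param targets Normalized half-times, one per row of `features`.
#' @param num_trees Random-forest size (default 500).
#' @param seed RNG seed for the forest (deterministic training).
#' @return Object of class `surrogate_model`.
#' @export
train_surrogate <- function(features, targets, num_trees = 500, seed = 1) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (nrow(features) < 8) stop("need >= 8 labelled molecules")
  if (length(targets) != nrow(features)) stop("targets/features mismatch")
  degenerate <- stats::var(targets) == 0
  if (degenerate) {
    warning("constant targets: surrogate is uncertainty-only")
    rf <- NULL
    resid <- targets - targets  # zeros
    const <- targets[1]
  } else {
    df <- data.frame(y = targets, features)
    rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                         seed = seed, num.threads = 1)
    resid <- targets - stats::predict(rf, df, num.threads = 1)$predictions
    const <- NA_real_
  }
  gp <- gp_fit(features, resid)
  structure(list(rf = rf, gp = gp, const = const,
                 feature_names = colnames(features)),
            class = "surrogate_model")
}

#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  base <- if (is.null(object$rf)) rep(object$const, nrow(newdata)) else {
    df <- data.frame(newdata)
    colnames(df) <- object$feature_names
    stats::predict(object$rf, df, num.threads = 1)$predictions
  }
  g <- predict(object$gp, newdata)
  list(mean = base + g$mean, sd = g$sd)
}

#' Upper-confidence-bound acquisition score
#'
#' score = predicted mean + beta * predictive SD; maximizing it trades off
#' exploitation (high predicted normalized half-time) against exploration
#' (high model uncertainty), with beta the exploration weight.
#'
#' @param pred_mean,pred_sd Numeric vectors.
#' @param beta Uncertainty weight >= 0.
#' @return Numeric scores.
#' @export
acquisition_score <- function(pred_mean, pred_sd, beta = 1) {
  if (length(beta) != 1 || is.na(beta) || beta < 0) {
    stop("beta must be a single non-negative number")
  }
  if (any(pred_sd < 0)) stop("pred_sd must be >= 0")
  pred_mean + beta * pred_sd
}

#' Select the next batch of molecules to test
#'
#' Greedy top-k by acquisition score over the untested pool, with ties
#' broken by id in lexicographic order, and an optional diversity filter
#' that rejects a candidate whose Tanimoto similarity to an
#' already-selected batch member exceeds `diversity_cutoff`.
#'
#' @param scores Named numeric vector (names = molecule ids) of
#'   acquisition scores for the untested pool.
#' @param batch_size Number of molecules to select.
#' @param fp Optional fingerprint matrix (rownames = ids) enabling the
#'   diversity filter.
#' @param diversity_cutoff Maximum allowed similarity inside the batch
#'   (default 1 = no filtering).
#' @return Character vector of selected ids.
#' @export
select_batch <- function(scores, batch_size, fp = NULL,
                         diversity_cutoff = 1) {
  if (length(scores) < batch_size) stop("untested pool smaller than batch")
  ord <- order(-scores, names(scores))
  if (is.null(fp) || diversity_cutoff >= 1) {
    return(names(scores)[ord[seq_len(batch_size)]])
  }
  sel <- character(0)
  for (i in ord) {
    id <- names(scores)[i]
    if (length(sel)) {
      s <- tanimoto_matrix(fp[id, , drop = FALSE], fp[sel, , drop = FALSE])
      if (max(s) > diversity_cutoff) next
    }
    sel <- c(sel, id)
    if (length(sel) == batch_size) break
  }
  if (length(sel) < batch_size) {
    # diversity filter exhausted the pool: fill greedily
    rest <- setdiff(names(scores)[ord], sel)
    sel <- c(sel, rest[seq_len(batch_size - length(sel))])
  }
  sel
}
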