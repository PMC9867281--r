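# Muscle-synergy extraction by non-negative matrix factorization and the
# derived performance indicators: reconstruction quality (uncentered VAF),
# full width at half maximum and center of activity of the basic patterns.

#' Uncentered variance accounted for
#'
#' `vaf = 1 - sum((E - Ehat)^2) / sum(E^2)`. This uncentered form is the
#' standard reconstruction-quality index for non-negative envelope data; it
#' is 1 for a perfect reconstruction and 0 for the zero reconstruction.
#'
#' @param E observed non-negative matrix.
#' @param Ehat reconstruction, same shape.
#' @return scalar in `(-Inf, 1]`.
#' @export
vaf <- function(E, Ehat) {
  if (!identical(dim(as.matrix(E)), dim(as.matrix(Ehat))))
    stop("E and Ehat must have the same shape")
  ss <- sum(E^2)
  if (ss == 0) stop("sum of squares of E is zero; VAF undefined")
  1 - sum((E - Ehat)^2) / ss
}

#' Full width at half maximum of a basic activation pattern
#'
#' The pattern minimum is subtracted first; the FWHM is then the fraction of
#' grid points at or above half of the resulting maximum, in % gait cycle.
#' All supra-half-maximum points count, not only the contiguous peak region.
#'
#' @param pattern non-negative numeric vector over the cycle grid.
#' @param eps flatness tolerance: patterns with `max - min < eps` have no
#'   defined width and return `NA`.
#' @return FWHM in % gait cycle (`[0, 100]`), or `NA` for a flat pattern.
#' @export
fwhm <- function(pattern, eps = 1e-12) {
  g <- length(pattern)
  if (g < 2) stop("pattern must have at least 2 points")
  p <- pattern - min(pattern)
  if (max(p) < eps) return(NA_real_)
  100 * sum(p >= max(p) / 2) / g
}

#' Center of activity of a basic activation pattern
#'
#' The cycle is treated as a circle (grid point t at angle `2*pi*t/grid`);
#' the CoA is the direction of the activation-weighted resultant vector,
#' mapped back to % gait cycle. Circular statistics make the CoA well defined
#' for activity spanning the cycle wrap.
#'
#' @param pattern non-negative numeric vector over the cycle grid.
#' @param eps degeneracy tolerance on the resultant length relative to the
#'   total activation; a (near-)uniform pattern returns `NA`.
#' @return CoA in % gait cycle (`[0, 100)`), or `NA` when degenerate.
#' @export
coa <- function(pattern, eps = 1e-9) {
  g <- length(pattern)
  if (g < 2) stop("pattern must have at least 2 points")
  if (any(pattern < 0)) stop("pattern must be non-negative")
  tot <- sum(pattern)
  if (tot <= 0) stop("pattern sum must be positive")
  theta <- 2 * pi * (seq_len(g) - 1) / g
  S <- sum(pattern * sin(theta))
  C <- sum(pattern * cos(theta))
  if (sqrt(S^2 + C^2) < eps * tot) return(NA_real_)
  ang <- atan2(S, C) %% (2 * pi)
  100 * ang / (2 * pi)
}

# run expr with the global RNG seeded, then restore the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# multiplicative-update NMF for min ||E - WH||_F^2, E >= 0
nmf_mu <- function(E, k, max_iter = 2000, tol = 1e-6) {
  n <- nrow(E); m <- ncol(E)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(E) / k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m) * sqrt(mean(E) / k)
  sse_old <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    H <- H * (crossprod(W, E)) / (crossprod(W) %*% H + eps)
    W <- W * (E %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (iter %% 10L == 0L || iter == max_iter) {
      sse <- sum((E - W %*% H)^2)
      if (is.finite(sse_old) && abs(sse_old - sse) <= tol * max(sse_old, eps))
        break
      sse_old <- sse
    }
  }
  list(W = W, H = H, sse = sum((E - W %*% H)^2), iter = iter)
}

#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factors a muscle x time matrix of cycle-normalized envelopes (cycles
#' concatenated along time) as `E ~ W H` with `W, H >= 0`, using
#' multiplicative updates minimizing squared Frobenius error, best of
#' `restarts` seeded random initializations. Each muscle's envelope is first
#' normalized to its trial maximum so that high-amplitude channels do not
#' dominate the fit. Synergy vectors (columns of `W`) are scaled to unit
#' maximum, with the scale pushed into `H`; the reported basic patterns are
#' the cycle averages of the fitted time courses.
#'
#' @param cm a `cycle_matrix` of envelopes (from [normalize_cycles()]), or a
#'   non-negative muscle x time matrix.
#' @param n_syn number of synergies (default 4: four basic patterns explain
#'   most lower-limb EMG variability during gait).
#' @param restarts number of random initializations (default 20).
#' @param seed RNG seed for the initializations.
#' @param max_iter,tol convergence controls: stop when the relative SSE
#'   change falls below `tol` or after `max_iter` iterations.
#' @param normalize_muscles divide each muscle by its trial maximum before
#'   fitting (default `TRUE`).
#' @return object of class `synergy_fit` with elements `W`
#'   (`n_muscles x n_syn`), `H` (`n_syn x grid` cycle-averaged basic
#'   patterns), `H_full` (fitted time courses), `vaf`, `n_syn`, `muscles`,
#'   `grid`, `n_cycles`, and restart metadata.
#' @export
extract_synergies <- function(cm, n_syn = 4, restarts = 20, seed = 1,
                              max_iter = 2000, tol = 1e-6,
                              normalize_muscles = TRUE) {
  if (n_syn < 1) stop("n_syn must be >= 1")
  if (inherits(cm, "cycle_matrix")) {
    d <- dim(cm$data)
    grid <- cm$grid; n_cycles <- d[1]; muscles <- cm$channel_map
    # concatenate cycles along time: muscle x (n_cycles * grid)
    E <- t(matrix(aperm(cm$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3],
                  dimnames = list(NULL, muscles)))
  } else {
    E <- as.matrix(cm)
    muscles <- rownames(E)
    if (is.null(muscles)) muscles <- paste0("m", seq_len(nrow(E)))
    grid <- ncol(E); n_cycles <- 1L
  }
  if (any(E < 0)) stop("input must be non-negative")
  if (n_syn > nrow(E)) stop("n_syn cannot exceed the number of muscles")
  scale_mu <- apply(E, 1, max)
  if (normalize_muscles) {
    nz <- scale_mu > 0
    E[nz, ] <- E[nz, , drop = FALSE] / scale_mu[nz]
  }
  fits <- lapply(seq_len(restarts), function(r) {
    with_seed(seed + r - 1L, nmf_mu(E, n_syn, max_iter, tol))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  W <- best$W; H <- best$H
  # unit-max synergy vectors; scale pushed into H so W %*% H is unchanged
  cmax <- apply(W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(W, 2, cmax, "/")
  H <- sweep(H, 1, cmax, "*")
  H_avg <- if (n_cycles > 1) {
    t(apply(H, 1, function(h) colMeans(matrix(h, n_cycles, grid,
                                              byrow = TRUE))))
  } else H
  if (n_syn == 1) H_avg <- matrix(H_avg, nrow = 1)
  rownames(W) <- muscles
  colnames(W) <- rownames(H_avg) <- paste0("syn", seq_len(n_syn))
  structure(list(
    W = W, H = H_avg, H_full = H, E = E, vaf = vaf(E, W %*% H),
    n_syn = n_syn, muscles = muscles, grid = grid, n_cycles = n_cycles,
    muscle_scale = scale_mu, normalized = normalize_muscles,
    restarts = restarts, seed = seed, best_sse = best$sse,
    iterations = best$iter
  ), class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf(
    "<synergy_fit> %d synergies, %d muscles, %d cycles; VAF = %.4f\n",
    x$n_syn, length(x$muscles), x$n_cycles, x$vaf))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  ps <- pattern_stats(object)
  out <- list(vaf = object$vaf, W = object$W, pattern_stats = ps,
              n_syn = object$n_syn, best_sse = object$best_sse,
              restarts = object$restarts)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  cat(sprintf("Muscle synergies (NMF, best of %d restarts)\n", x$restarts))
  cat(sprintf("  reconstruction quality (VAF): %.4f\n", x$vaf))
  cat("  synergy vectors W:\n")
  print(round(x$W, 3))
  cat("  basic patterns:\n")
  print(transform(x$pattern_stats, fwhm = round(fwhm, 2),
                  coa = round(coa, 2)))
  invisible(x)
}

#' @export
coef.synergy_fit <- function(object, ...) object$W

#' @export
fitted.synergy_fit <- function(object, ...) object$W %*% object$H_full

#' @export
residuals.synergy_fit <- function(object, ...) object$E - fitted(object)

#' @export
predict.synergy_fit <- function(object, patterns = NULL, ...) {
  if (is.null(patterns)) return(object$W %*% object$H)
  object$W %*% patterns
}

#' FWHM and CoA of a fit's basic patterns
#'
#' @param fit a `synergy_fit` (or an `n_syn x grid` non-negative matrix).
#' @return data frame: `synergy`, `fwhm`, `coa` (% gait cycle; `NA` when
#'   degenerate).
#' @export
pattern_stats <- function(fit) {
  H <- if (inherits(fit, "synergy_fit")) fit$H else as.matrix(fit)
  data.frame(
    synergy = seq_len(nrow(H)),
    fwhm = apply(H, 1, fwhm),
    coa = apply(H, 1, coa)
  )
}
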