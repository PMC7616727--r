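# Internal helpers shared across modules.

#' @keywords internal
stop_with <- function(class, msg, call. = FALSE) {
  cond <- structure(class = c(class, "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

stop_format <- function(msg) stop_with("mrsdyn_format_error", msg)
stop_shape <- function(msg) stop_with("mrsdyn_shape_error", msg)
stop_domain <- function(msg) stop_with("mrsdyn_domain_error", msg)

#' fftshift permutation: reorder DFT output so frequency ascends from
#' -bandwidth/2. Returns 1-based indices into the unshifted fft output.
#' @keywords internal
fftshift_indices <- function(n) {
  half <- floor(n / 2)
  c((half + 1L):n, 1L:half)
}

#' Deterministic child-seed derivation
#'
#' Splittable counter scheme used by the Monte Carlo harness so that
#' every repetition (and every strategy within one repetition) sees a
#' reproducible stream; results stay inside the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param i child index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 7919) %% 2147483629)
}

#' Non-negative least squares by cyclic coordinate descent; adequate for
#' the small (K <= 25) initialisation problems it serves.
#' @keywords internal
nnls_cd <- function(A, b, max_iter = 200L, tol = 1e-10) {
  nnls_cd_pre(crossprod(A), crossprod(A, b), max_iter, tol)
}

# normal-equation form (precomputed A'A and A'b)
nnls_cd_pre <- function(AtA, Atb, max_iter = 200L, tol = 1e-10) {
  K <- ncol(AtA)
  x <- rep(0, K)
  d <- diag(AtA)
  d[d < 1e-300] <- 1e-300
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(K)) {
      xk_new <- max(0, x[k] + (Atb[k] - sum(AtA[k, ] * x)) / d[k])
      delta <- max(delta, abs(xk_new - x[k]))
      x[k] <- xk_new
    }
    if (delta < tol * (1 + max(abs(x)))) break
  }
  x
}

#' Guarded symmetric pseudo-inverse via eigendecomposition. Flags
#' near-null directions.
#' @keywords internal
pinv_sym <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values), 1e-300)
  keep <- e$values > tol * lmax
  inv_vals <- ifelse(keep, 1 / pmax(e$values, 1e-300), 0)
  list(inv = e$vectors %*% (inv_vals * t(e$vectors)),
       rank = sum(keep),
       degenerate = which(!keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
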