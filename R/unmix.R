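#' @title Constrained linear unmixing
#' @description Solvers for the per-pixel linear mixing model
#'   r = sum_i a_i * R_i + e under four constraint modes: ordinary least
#'   squares (`ols`), sum-to-one only (`sto`), non-negative only (`nnls`),
#'   and fully constrained (`fcls`, non-negativity + sum-to-one). The FCLS
#'   route is an active-set non-negative least-squares solve on a system
#'   augmented with a heavily weighted sum-to-one row, followed by an exact
#'   equality-constrained polish on the final support, so the returned
#'   fractions satisfy the simplex constraints to machine precision (a final
#'   clamp absorbs only floating-point dust of at most 1e-9).
#' @name linear_unmixing
NULL

UNMIX_MODES <- c("ols", "sto", "nnls", "fcls")

# Lawson-Hanson active set on the normal equations:
# minimize 1/2 x'Gx - c'x subject to x >= 0.
nnls_normal <- function(G, cvec, tol = NULL) {
  K <- length(cvec)
  if (is.null(tol)) tol <- 1e-12 * max(abs(diag(G)))
  x <- numeric(K)
  P <- logical(K)
  w <- cvec                     # negative gradient at x = 0
  for (outer in seq_len(30 * K)) {
    cand <- which(!P & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      z <- numeric(K)
      z[P] <- solve(G[P, P, drop = FALSE], cvec[P])
      if (all(z[P] > 0)) break
      neg <- P & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- z
    w <- cvec - G %*% x
  }
  x
}

# library design pieces on the shared valid bands
unmix_design <- function(lib, bands) {
  A <- t(lib$spectra[, bands, drop = FALSE])   # B_valid x K
  G0 <- crossprod(A)
  sv <- svd(A, nu = 0, nv = 0)$d               # rank check on A, not A'A
  if (min(sv) / max(sv) < 1e-10) {
    ang <- separability_matrix(lib)
    diag(ang) <- Inf
    ij <- sort(which(ang == min(ang), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "endmember library is rank-deficient; classes '%s' and '%s' are near-collinear",
      lib$class_names[ij[1]], lib$class_names[ij[2]]))
  }
  list(A = A, G0 = G0, K = ncol(A), B = nrow(A))
}

solve_modes <- function(dsg, cvec, mode) {
  K <- dsg$K
  switch(mode,
    ols = drop(solve(dsg$G0, cvec)),
    sto = {
      # KKT system for equality-constrained least squares
      M <- rbind(cbind(dsg$G0, rep(1, K)), c(rep(1, K), 0))
      drop(solve(M, c(cvec, 1)))[seq_len(K)]
    },
    nnls = drop(nnls_normal(dsg$G0, cvec)),
    fcls = {
      # sum-to-one augmentation weight: large enough to pin the constraint,
      # small enough that gradient cancellation noise (~ lam2 * eps) stays
      # below the entry tolerance, which must scale with the *data* block
      # so that tiny true fractions still enter the active set
      g0max <- max(diag(dsg$G0))
      lam2 <- 1e6 * g0max
      x <- nnls_normal(dsg$G0 + lam2, cvec + lam2, tol = 1e-8 * g0max)
      # exact polish: equality-constrained solve on the active support
      P <- x > 1e-9
      if (any(P)) {
        kP <- sum(P)
        M <- rbind(cbind(dsg$G0[P, P, drop = FALSE], rep(1, kP)),
                   c(rep(1, kP), 0))
        z <- drop(solve(M, c(cvec[P], 1)))[seq_len(kP)]
        if (all(z >= -1e-9)) {
          x[] <- 0
          x[P] <- z
        }
      }
      x[x < 0 & x > -1e-9] <- 0          # clamp floating-point dust only
      x[x > 1 & x < 1 + 1e-9] <- 1
      x
    },
    stop("unknown mode: ", mode))
}

#' Unmix a single pixel spectrum
#'
#' Finds the fractional abundances minimizing the squared reconstruction
#' error over the shared valid bands, under the chosen constraint mode, and
#' reports the root-mean-square residual.
#'
#' @param r pixel spectrum on the library's band axis (full length; only
#'   valid bands enter the fit).
#' @param lib an [endmember_library()].
#' @param mode `"ols"`, `"sto"`, `"nnls"` or `"fcls"`.
#' @return list with `fractions` (named K-vector) and `rmse`.
#' @export
unmix_pixel <- function(r, lib, mode = "fcls") {
  mode <- match.arg(mode, UNMIX_MODES)
  stopifnot(inherits(lib, "endmember_library"))
  if (length(r) != ncol(lib$spectra))
    stop("pixel spectrum band axis (", length(r),
         ") does not match the library (", ncol(lib$spectra), ")")
  bands <- which(lib$band_valid)
  if (nrow(lib$spectra) >= length(bands))
    stop("need K < number of valid bands")
  dsg <- unmix_design(lib, bands)
  rb <- r[bands]
  cvec <- drop(crossprod(dsg$A, rb))
  x <- solve_modes(dsg, cvec, mode)
  res2 <- sum(rb^2) - 2 * sum(x * cvec) + drop(t(x) %*% dsg$G0 %*% x)
  list(fractions = setNames(x, lib$class_names),
       rmse = sqrt(max(res2, 0) / dsg$B))
}

#' Unmix a reflectance cube
#'
#' Applies the per-pixel constrained solve to every valid pixel of the cube
#' (invalid pixels propagate as invalid) and assembles per-class fractional
#' abundance maps plus a per-pixel reconstruction-RMSE map. A summary of the
#' mean RMSE and of any constraint violations is attached as attributes
#' `"mean_rmse"` and `"constraint_violations"`.
#'
#' @param cube a [spectral_cube()].
#' @param lib an [endmember_library()]; wavelength axis must match the cube.
#' @param mode constraint mode, see [unmix_pixel()].
#' @return A [fraction_stack()].
#' @export
unmix_cube <- function(cube, lib, mode = "fcls") {
  mode <- match.arg(mode, UNMIX_MODES)
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(lib, "endmember_library"))
  if (length(cube$wavelengths_nm) != length(lib$wavelengths_nm) ||
      any(cube$wavelengths_nm != lib$wavelengths_nm))
    stop("cube and library wavelength axes differ")
  bands <- which(cube$band_valid & lib$band_valid)
  K <- nrow(lib$spectra)
  if (K >= length(bands)) stop("need K < number of shared valid bands")
  dsg <- unmix_design(lib, bands)
  pm <- cube_pixel_matrix(cube, bands)
  Y <- pm$values                               # n_valid x B_valid
  n <- nrow(Y)
  d <- dim(cube$reflectance)
  X <- matrix(NA_real_, n, K)
  Cmat <- Y %*% dsg$A                          # n x K of A'y per pixel
  rr <- rowSums(Y^2)
  for (i in seq_len(n))
    X[i, ] <- solve_modes(dsg, Cmat[i, ], mode)
  res2 <- rr - 2 * rowSums(X * Cmat) +
    rowSums((X %*% dsg$G0) * X)
  rmse_v <- sqrt(pmax(res2, 0) / dsg$B)
  fr <- array(NA_real_, c(d[1], d[2], K))
  frm <- matrix(fr, d[1] * d[2], K)
  frm[pm$pixel_index, ] <- X
  rmse <- matrix(NA_real_, d[1], d[2])
  rmse[pm$pixel_index] <- rmse_v
  viol <- if (mode == "fcls")
    sum(abs(rowSums(X) - 1) > 1e-6 | X < -1e-9)
  else if (mode == "nnls") sum(X < -1e-9) else 0L
  out <- fraction_stack(array(frm, c(d[1], d[2], K)), lib$class_names,
                        residual_rmse = rmse, mode = mode,
                        pixel_valid = cube$pixel_valid,
                        pixel_size_m = cube$pixel_size_m,
                        origin_xy = cube$origin_xy,
                        crs_label = cube$crs_label)
  attr(out, "mean_rmse") <- if (n) mean(rmse_v) else NA_real_
  attr(out, "n_pixels_processed") <- n
  attr(out, "constraint_violations") <- viol
  out
}

#' Brute-force simplex-grid unmixing (test oracle)
#'
#' Exhaustively evaluates the squared reconstruction error on the simplex
#' lattice of spacing `step` and returns the minimizing lattice point.
#' Intended as an independent reference for the constrained solver; guarded
#' to K <= 4.
#'
#' @param r pixel spectrum on the library's band axis.
#' @param lib an [endmember_library()].
#' @param step lattice spacing; `1/step` must be integral.
#' @return named K-vector of fractions; attribute `"n_evaluated"` carries
#'   the lattice size.
#' @export
brute_force_unmix <- function(r, lib, step = 0.01) {
  stopifnot(inherits(lib, "endmember_library"))
  K <- nrow(lib$spectra)
  if (K > 4) stop("brute-force search is guarded to K <= 4")
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) stop("1/step must be integral")
  m <- as.integer(round(m))
  bands <- which(lib$band_valid)
  dsg <- unmix_design(lib, bands)
  rb <- r[bands]
  cvec <- drop(crossprod(dsg$A, rb))
  comp <- simplex_lattice(m, K)                # n x K integer compositions
  X <- comp / m
  obj <- rowSums((X %*% dsg$G0) * X) - 2 * drop(X %*% cvec)
  best <- X[which.min(obj), ]
  structure(setNames(best, lib$class_names), n_evaluated = nrow(X))
}

# all K-part compositions of m (rows sum to m)
simplex_lattice <- function(m, K) {
  if (K == 1) return(matrix(m, 1, 1))
  parts <- lapply(0:m, function(i)
    cbind(i, simplex_lattice(m - i, K - 1)))
  out <- do.call(rbind, parts)
  dimnames(out) <- NULL
  out
}
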