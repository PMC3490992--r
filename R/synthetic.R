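## Synthetic data: analytic and randomized tooth-row-like surfaces with known
## orientation-patch structure, and specimen tables with the statistical
## structure the GLS candidate models assume.

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic test surface
#'
#' Four families of surfaces with analytically known orientation structure:
#' `"plane"` (one aspect everywhere: OPC 1); `"pyramid"` (`n_faces` planar
#' faces meeting at an apex, faces centred on the compass bins); `"cone"`
#' (a faceted cone, 8 faces by default); `"cusp_field"` (Gaussian cusps on a
#' gentle base plane, centres kept at least 4 cusp widths apart, giving a
#' tunable complexity ladder: each isolated cusp contributes up to one patch
#' per occupied bin).
#'
#' @param kind `"plane"`, `"pyramid"`, `"cone"` or `"cusp_field"`.
#' @param n_rows,n_cols grid size (cells).
#' @param spacing grid step (mm).
#' @param slope tangent of the slope for planes, pyramid/cone flanks.
#' @param azimuth downhill azimuth of the plane, degrees clockwise from grid
#'   north.
#' @param n_faces radial faces of a pyramid (4) or cone (8).
#' @param n_cusps,cusp_width,cusp_height cusp count, Gaussian SD (mm) and
#'   height range (mm) for `"cusp_field"`.
#' @param base_slope tangent of the base plane under a cusp field.
#' @param seed RNG seed; output is deterministic for a fixed spec.
#' @return A list of class `surface_spec`.
#' @export
surface_spec <- function(kind = c("plane", "pyramid", "cone", "cusp_field"),
                         n_rows = 63L, n_cols = 63L, spacing = 0.05,
                         slope = 0.5, azimuth = 0,
                         n_faces = if (match.arg(kind) == "pyramid") 4L else 8L,
                         n_cusps = 5L, cusp_width = 0.15,
                         cusp_height = c(0.5, 1.5), base_slope = 0.02,
                         seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_rows = check_count(n_rows, "n_rows"),
                 n_cols = check_count(n_cols, "n_cols"), spacing = spacing,
                 slope = slope, azimuth = azimuth,
                 n_faces = check_count(n_faces, "n_faces"),
                 n_cusps = check_count(n_cusps, "n_cusps"),
                 cusp_width = cusp_width, cusp_height = cusp_height,
                 base_slope = base_slope, seed = as.integer(seed)),
            class = "surface_spec")
}

#' Generate a synthetic surface
#'
#' @param spec a [surface_spec()].
#' @return A [height_map()].
#' @examples
#' opc <- compute_opc(make_surface(surface_spec("pyramid", n_faces = 4)))
#' opc  # four faces centred on four bins
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; h <- spec$spacing
  y <- ((seq_len(nr) - 1) - (nr - 1) / 2) * h     # north coordinate per row
  x <- ((seq_len(nc) - 1) - (nc - 1) / 2) * h     # east coordinate per col
  Y <- matrix(y, nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)
  vals <- switch(spec$kind,
    plane = {
      az <- spec$azimuth * pi / 180
      -spec$slope * (sin(az) * X + cos(az) * Y)
    },
    pyramid = ,
    cone = {
      ks <- seq_len(spec$n_faces) - 1
      az <- ks * 2 * pi / spec$n_faces
      ## z = -slope * max_k (face direction_k . p): planar faces whose
      ## downhill azimuths sit on the bin centres when n_faces divides 360
      ## evenly into the binning
      m <- matrix(-Inf, nr, nc)
      for (a in az) m <- pmax(m, cos(a) * Y + sin(a) * X)
      -spec$slope * m
    },
    cusp_field = with_seed(spec$seed, {
      base <- -spec$base_slope * Y
      w <- spec$cusp_width
      margin <- 2 * w
      lo_y <- min(y) + margin; hi_y <- max(y) - margin
      lo_x <- min(x) + margin; hi_x <- max(x) - margin
      if (lo_y >= hi_y || lo_x >= hi_x)
        stop("grid too small for the requested cusp width", call. = FALSE)
      centres <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(centres) < spec$n_cusps) {
        cand <- c(stats::runif(1, lo_y, hi_y), stats::runif(1, lo_x, hi_x))
        if (!nrow(centres) ||
            min(sqrt(rowSums((centres - matrix(cand, nrow(centres), 2,
                                               byrow = TRUE))^2))) >= 4 * w) {
          centres <- rbind(centres, cand)
        }
        tries <- tries + 1L
        if (tries > 1e4)
          stop("could not place cusps >= 4 widths apart; use fewer cusps",
               call. = FALSE)
      }
      heights <- stats::runif(spec$n_cusps, spec$cusp_height[1],
                              spec$cusp_height[2])
      z <- base
      for (i in seq_len(spec$n_cusps)) {
        r2 <- (Y - centres[i, 1])^2 + (X - centres[i, 2])^2
        z <- z + heights[i] * exp(-r2 / (2 * w^2))
      }
      z
    })
  )
  height_map(vals, spacing_row = h, spacing_col = h,
             origin = c(min(y), min(x)))
}

#' Parameters of the specimen-table simulator
#'
#' Defaults reproduce the moments of the packaged 34-specimen table:
#' `(ln_lower, rt, rd)` are drawn from a multivariate normal with those
#' means, SDs and correlations, and `ln_upper` is generated under the
#' best-supported candidate structure
#' `ln_upper = beta0 + beta1 ln_lower + beta_rt rt + beta_rd rd + eps`.
#'
#' @param n specimens.
#' @param beta0,beta1,beta_rt,beta_rd generating coefficients (intercept,
#'   opposing-OPCR slope, relative lateral translation, relative ventral
#'   rotational distance).
#' @param sigma residual SD of `eps` (> 0).
#' @param rho range of the Gaussian residual correlation over predictor
#'   space; 0 (default) gives independent errors.
#' @param mu,sds means and SDs of `(ln_lower, rt, rd)`.
#' @param cor_mat their 3 x 3 correlation matrix (positive definite).
#' @param ln_w_mean,ln_w_sd log-normal glenoid-width distribution.
#' @param seed RNG seed.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n = 34L, beta0 = 0.89, beta1 = 0.79,
                              beta_rt = 0, beta_rd = -0.22, sigma = 0.11,
                              rho = 0,
                              mu = c(4.544, -2.903, -2.213),
                              sds = c(0.594, 0.400, 0.364),
                              cor_mat = matrix(c(1, 0.462, -0.021,
                                                 0.462, 1, 0.592,
                                                 -0.021, 0.592, 1), 3, 3),
                              ln_w_mean = 3.814, ln_w_sd = 0.512,
                              seed = 1L) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  ev <- eigen(cor_mat, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("`cor_mat` must be positive definite", call. = FALSE)
  structure(list(n = check_count(n, "n"), beta0 = beta0, beta1 = beta1,
                 beta_rt = beta_rt, beta_rd = beta_rd, sigma = sigma,
                 rho = rho, mu = mu, sds = sds, cor_mat = cor_mat,
                 ln_w_mean = ln_w_mean, ln_w_sd = ln_w_sd,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a specimen table with known generating structure
#'
#' Emits a table with the packaged fixture's schema whose derived measures
#' follow the stated generating model, for parameter-recovery and model-
#' selection calibration studies. The generating truth is attached as
#' `attr(, "truth")`.
#'
#' @param params a [simulation_params()].
#' @return A `specimen_table` with `params$n` rows.
#' @export
simulate_specimens <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  with_seed(p$seed, {
    Sigma <- diag(p$sds) %*% p$cor_mat %*% diag(p$sds)
    Z <- matrix(stats::rnorm(p$n * 3), p$n, 3) %*% chol(Sigma)
    Z <- sweep(Z, 2, p$mu, "+")
    ln_lower <- Z[, 1]; rt <- Z[, 2]; rd <- Z[, 3]
    if (p$rho > 0) {
      D <- as.matrix(stats::dist(cbind(ln_lower, rt, rd)))
      Se <- p$sigma^2 * exp(-(D / p$rho)^2)
      eps <- drop(crossprod(chol(Se), stats::rnorm(p$n)))
    } else {
      eps <- stats::rnorm(p$n, sd = p$sigma)
    }
    ln_upper <- p$beta0 + p$beta1 * ln_lower + p$beta_rt * rt +
      p$beta_rd * rd + eps
    w <- exp(stats::rnorm(p$n, p$ln_w_mean, p$ln_w_sd))
    t <- w * exp(rt)
    d <- w * exp(rd)
    a <- atan2(t, d) * 180 / pi          # in (0, 90); surrogate occlusal angle
    n_carn <- round(p$n * 20 / 34)
    ord <- rep(c("Carnivora", "Dasyuromorphia"), c(n_carn, p$n - n_carn))
    df <- data.frame(
      order_name = ord, family = "Simulatidae", genus = "Simulator",
      species = sprintf("sp%03d", seq_len(p$n)), collection = "SIM",
      number = as.character(seq_len(p$n)),
      n_upper_teeth = ifelse(ord == "Carnivora", 3L, 4L),
      n_lower_teeth = ifelse(ord == "Carnivora", 2L, 4L),
      upper_opcr = exp(ln_upper), lower_opcr = exp(ln_lower),
      t = t, d = d, a = a, w = w, stringsAsFactors = FALSE)
    validate_specimens(df)
    class(df) <- c("specimen_table", "data.frame")
    attr(df, "truth") <- list(beta = c(p$beta0, p$beta1, p$beta_rt, p$beta_rd),
                              sigma = p$sigma, rho = p$rho, seed = p$seed)
    df
  })
}
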