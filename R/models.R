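#' Fit a demographic-rate GAM
#'
#' Models one demographic response — height growth, crown expansion (both
#' Gaussian) or death (binomial, logit link) — as a penalized cubic
#' regression spline in tree size plus linear parametric terms for
#' topographic wetness, neighbourhood canopy height and pulse-density
#' difference. The smoothing parameter is selected by REML. The linear
#' covariates are centred and scaled to unit variance before fitting so
#' their coefficients are directly comparable; the standardization constants
#' are stored with the fit so predictions can be made on the raw scale.
#'
#' @param data data.frame with columns `size`, `twi`, `neigh`, `pd_diff`
#'   and the response column; rows with missing values are dropped
#'   (complete-case analysis).
#' @param response one of `"delta_h_decade"`, `"delta_a_decade"`, `"died"`.
#' @param k basis dimension of the size smooth (default 10).
#' @param sp optional fixed smoothing parameter (e.g. very large values
#'   force the smooth to its linear limit); `NULL` selects by REML.
#' @return object of class `demog_gam`: the mgcv fit, standardization
#'   constants, covariate quantiles and the training size range.
#' @export
fit_gam <- function(data, response = c("delta_h_decade", "delta_a_decade",
                                       "died"),
                    k = 10, sp = NULL) {
  response <- match.arg(response)
  need <- c("size", "twi", "neigh", "pd_diff", response)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, need]), need]
  if (nrow(d) < 30) stop("too few complete cases to fit a GAM")
  binomial_fit <- response == "died"
  y <- if (binomial_fit) as.integer(d[[response]]) else d[[response]]
  if (binomial_fit && (all(y == 0) || all(y == 1)))
    stop("complete separation: response is all-dead or all-alive")
  scaling <- lapply(d[c("twi", "neigh", "pd_diff")], function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  if (any(vapply(scaling, function(s) s["sd"] == 0, logical(1))))
    stop("rank deficiency: a covariate is constant")
  dd <- data.frame(
    y = y, size = d$size,
    twi_z = (d$twi - scaling$twi["mean"]) / scaling$twi["sd"],
    neigh_z = (d$neigh - scaling$neigh["mean"]) / scaling$neigh["sd"],
    pd_z = (d$pd_diff - scaling$pd_diff["mean"]) / scaling$pd_diff["sd"])
  fam <- if (binomial_fit) stats::binomial("logit") else stats::gaussian()
  fit <- mgcv::gam(y ~ s(size, bs = "cr", k = k) + twi_z + neigh_z + pd_z,
                   data = dd, family = fam, method = "REML",
                   sp = if (is.null(sp)) NULL else c(sp))
  st <- summary(fit)
  structure(list(
    fit = fit, response = response,
    family = if (binomial_fit) "binomial-logit" else "gaussian-identity",
    scaling = scaling,
    coefficients = data.frame(
      term = rownames(st$p.table),
      estimate = st$p.table[, 1], se = st$p.table[, 2],
      statistic = st$p.table[, 3], p_value = st$p.table[, 4],
      row.names = NULL),
    smooth_edf = sum(st$edf),
    size_range = range(d$size),
    quantiles = lapply(d[c("size", "twi", "neigh", "pd_diff")],
                       stats::quantile,
                       probs = c(0.05, 0.5, 0.95), names = FALSE),
    n = nrow(d)),
    class = "demog_gam")
}

#' @export
print.demog_gam <- function(x, ...) {
  cat("<demog_gam> ", x$response, " ~ s(size) + twi + neigh + pd  [",
      x$family, "], n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 3)
  cat("smooth edf:", round(x$smooth_edf, 2), "\n")
  invisible(x)
}

#' Covariate coefficient on the raw (unstandardized) scale
#' @param object a `demog_gam`.
#' @param term `"twi"`, `"neigh"` or `"pd_diff"`.
#' @return named vector with `estimate` and `se` per raw covariate unit.
#' @export
raw_coefficient <- function(object, term = c("twi", "neigh", "pd_diff")) {
  term <- match.arg(term)
  zname <- c(twi = "twi_z", neigh = "neigh_z", pd_diff = "pd_z")[[term]]
  row <- object$coefficients[object$coefficients$term == zname, ]
  sd <- object$scaling[[term]]["sd"]
  c(estimate = row$estimate / unname(sd), se = row$se / unname(sd))
}

#' Covariate-conditioned prediction curves
#'
#' Predicted response over the training size range (5th to 95th percentile
#' by default) at the low (5th percentile), mean and high (95th percentile)
#' value of one covariate, holding the other covariate at its mean and the
#' pulse-density difference at raw zero (mapped through the stored
#' standardization constants). Binomial fits are back-transformed to
#' probabilities.
#'
#' @param object a `demog_gam`.
#' @param var covariate to profile, `"twi"` or `"neigh"`.
#' @param n_size number of size grid points.
#' @param size_range optional size range; values outside the training range
#'   are flagged in the `extrapolated` column.
#' @return data.frame with `size`, `level` (low/mean/high), `value` (raw
#'   covariate value) and `pred`.
#' @export
predict_conditional <- function(object, var = c("twi", "neigh"),
                                n_size = 100, size_range = NULL) {
  var <- match.arg(var)
  qs <- object$quantiles
  if (is.null(size_range))
    size_range <- c(qs$size[1], qs$size[3])
  sizes <- seq(size_range[1], size_range[2], length.out = n_size)
  z <- function(term, raw) {
    s <- object$scaling[[term]]
    (raw - s["mean"]) / s["sd"]
  }
  levels <- data.frame(
    level = c("low", "mean", "high"),
    value = c(qs[[var]][1],
              unname(object$scaling[[var]]["mean"]),
              qs[[var]][3]))
  other <- setdiff(c("twi", "neigh"), var)
  out <- do.call(rbind, lapply(seq_len(3), function(i) {
    nd <- data.frame(size = sizes,
                     twi_z = 0, neigh_z = 0,
                     pd_z = unname(z("pd_diff", 0)))
    nd[[paste0(c(twi = "twi", neigh = "neigh")[[var]], "_z")]] <-
      unname(z(var, levels$value[i]))
    nd[[paste0(other, "_z")]] <- 0
    data.frame(size = sizes, level = levels$level[i],
               value = levels$value[i],
               pred = as.numeric(mgcv::predict.gam(object$fit, nd,
                                                   type = "response")))
  }))
  out$extrapolated <- out$size < object$size_range[1] |
    out$size > object$size_range[2]
  out
}

#' Spatial correlogram of model residuals
#'
#' Binned Moran's I of the (deviance) residuals against pairwise distance,
#' with a permutation envelope: residuals are randomly relabelled across
#' locations `n_perm` times and the envelope is the 2.5--97.5% range of the
#' permuted statistics per distance class. Distance classes with fewer than
#' two pairs are dropped with a warning. For large models a random subset of
#' `max_points` locations is used (seeded, reproducible).
#'
#' @param object a `demog_gam` or a numeric vector of residuals.
#' @param x,y locations (m) of the residuals, in fit order (complete cases).
#' @param n_bins number of distance classes.
#' @param max_dist largest distance considered (default: half the maximum
#'   pairwise distance).
#' @param n_perm permutations for the envelope.
#' @param max_points subsample cap.
#' @param seed RNG seed for subsampling and permutation.
#' @return data.frame of class `correlogram`: per bin the distance range,
#'   pair count, Moran's I, envelope and an `outside_envelope` flag.
#' @export
residual_spatial_autocorrelation <- function(object, x, y, n_bins = 10,
                                             max_dist = NULL, n_perm = 199,
                                             max_points = 800, seed = 1L) {
  z <- if (inherits(object, "demog_gam"))
    stats::residuals(object$fit, type = "deviance") else as.numeric(object)
  if (length(z) != length(x) || length(z) != length(y))
    stop("residuals and coordinates differ in length")
  with_seed(seed, {
    if (length(z) > max_points) {
      keep <- sample.int(length(z), max_points)
      z <- z[keep]; x <- x[keep]; y <- y[keep]
    }
    n <- length(z)
    dm <- as.matrix(stats::dist(cbind(x, y)))
    if (is.null(max_dist)) max_dist <- max(dm) / 2
    brk <- seq(0, max_dist, length.out = n_bins + 1)
    ut <- upper.tri(dm)
    db <- findInterval(dm[ut], brk, rightmost.closed = TRUE)
    ij <- which(ut, arr.ind = TRUE)
    zc <- z - mean(z)
    denom <- sum(zc^2)
    moran_bin <- function(zz, sel) {
      zzc <- zz - mean(zz)
      (n / (2 * sum(sel))) *
        (2 * sum(zzc[ij[sel, 1]] * zzc[ij[sel, 2]])) / sum(zzc^2)
    }
    rows <- list()
    for (b in seq_len(n_bins)) {
      sel <- db == b
      npairs <- sum(sel)
      if (npairs < 2) {
        warning("distance class ", b, " has fewer than 2 pairs; dropped")
        next
      }
      obs <- moran_bin(z, sel)
      perm <- vapply(seq_len(n_perm),
                     function(i) moran_bin(z[sample.int(n)], sel),
                     numeric(1))
      env <- stats::quantile(perm, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, d_lo = brk[b], d_hi = brk[b + 1],
        n_pairs = npairs, moran_i = obs,
        env_lo = env[1], env_hi = env[2],
        outside_envelope = obs < env[1] | obs > env[2])
    }
    out <- do.call(rbind, rows)
    class(out) <- c("correlogram", "data.frame")
    out
  })
}
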