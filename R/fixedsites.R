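## Fixed-sites partition models: model A (one omega shared by all columns,
## i.e. M0) versus model B (partition-specific omega for a designated column
## set, e.g. the 10 key positions, sharing kappa and branch lengths).

#' Fit the fixed-sites models A and B and test them
#'
#' Model A constrains a single omega across all alignment columns (identical
#' to M0). Model B gives the designated partition (typically the key columns)
#' its own omega while sharing kappa and branch lengths, adding one free
#' parameter (`df = 1`); with `partition_kappa = TRUE` the partition also gets
#' its own kappa (`df = 2`).
#'
#' @param alignment A `codon_alignment`.
#' @param tree An `ape::phylo` over the alignment labels.
#' @param key_columns Integer vector of 1-based partition columns (non-empty,
#'   proper subset of the columns).
#' @param codon_freq Frequency scheme or 61-vector, as in [fit_site_model()].
#' @param partition_kappa Give the key partition its own kappa?
#' @param alpha Significance level for the tenable call.
#' @param restarts,seed,control As in [fit_site_model()].
#' @return List with `fit_A`, `fit_B` (classes `fixed_sites_fit`), and `lrt`.
#' @export
fixed_sites_fit <- function(alignment, tree, key_columns, codon_freq = "F3x4",
                            partition_kappa = FALSE, alpha = 0.05,
                            restarts = 1, seed = 1, control = list()) {
  validate_codon_alignment(alignment)
  nc <- alignment$column_count
  key_columns <- sort(unique(as.integer(key_columns)))
  if (length(key_columns) == 0) stop("empty key partition")
  if (any(key_columns < 1 | key_columns > nc)) stop("key columns out of range")
  if (length(key_columns) == nc) stop("key partition covers every column")
  dat <- prepare_fit_data(alignment, tree, codon_freq)

  is_key <- seq_len(nc) %in% key_columns
  ## per-pattern weights split by partition
  npat <- length(dat$weights)
  w_key <- tabulate(dat$map[is_key], npat)
  w_rest <- tabulate(dat$map[!is_key], npat)
  frac <- c(sum(is_key), sum(!is_key)) / nc
  bl0 <- dat$blens0

  negll <- function(theta, two_kappa) {
    wk <- exp(theta[1]); wr <- exp(theta[2])
    if (two_kappa) {
      kk <- exp(theta[3]); kr <- exp(theta[4]); off <- 4
    } else {
      kk <- kr <- exp(theta[3]); off <- 3
    }
    bl <- exp(theta[off + seq_along(bl0)])
    if (max(kk, kr) > 200 || any(bl > 50)) return(1e10)
    if (two_kappa) {
      llk <- class_logliks(dat, bl, kk, c(wk, wr), frac)[, 1]
      llr <- class_logliks(dat, bl, kr, c(wk, wr), frac)[, 2]
    } else {
      ll <- class_logliks(dat, bl, kk, c(wk, wr), frac)
      llk <- ll[, 1]; llr <- ll[, 2]
    }
    val <- -(sum(w_key * llk) + sum(w_rest * llr))
    if (!is.finite(val)) 1e10 else val
  }

  ctrl <- utils::modifyList(list(rel.tol = 1e-10, eval.max = 5000, iter.max = 1000),
                            control)
  run <- function(theta0, two_kappa) {
    best <- NULL
    for (r in seq_len(restarts + 1)) {
      th <- theta0
      if (r > 1) { set.seed(seed + r); th <- th + stats::rnorm(length(th), 0, 0.3) }
      opt <- tryCatch(stats::nlminb(th, negll, two_kappa = two_kappa, control = ctrl),
                      error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
        best <- opt
    }
    if (is.null(best)) stop("fixed-sites optimization failed")
    best
  }

  ## model A: one omega -> constrain w_key == w_rest by fitting M0
  fit_A0 <- fit_site_model(alignment, tree, "M0", codon_freq = codon_freq,
                           restarts = restarts, seed = seed, control = control)
  fit_A <- structure(list(model = "FS-A", lnL = fit_A0$lnL, np = fit_A0$np,
                          mle = list(omega = fit_A0$mle$omegas[1],
                                     kappa = fit_A0$mle$kappa),
                          tree = fit_A0$tree),
                     class = "fixed_sites_fit")

  w0 <- fit_A0$mle$omegas[1]
  theta0 <- c(log(w0), log(w0),
              if (partition_kappa) rep(log(fit_A0$mle$kappa), 2) else log(fit_A0$mle$kappa),
              log(pmax(fit_A0$tree$edge.length, 1e-6)))
  best <- run(theta0, partition_kappa)
  off <- if (partition_kappa) 4 else 3
  tr <- dat$tree; tr$edge.length <- exp(best$par[off + seq_along(bl0)])
  fit_B <- structure(list(
    model = "FS-B", lnL = -best$objective,
    np = fit_A$np + if (partition_kappa) 2L else 1L,
    mle = list(omega_key = exp(best$par[1]), omega_rest = exp(best$par[2]),
               kappa = exp(best$par[3]),
               kappa_rest = if (partition_kappa) exp(best$par[4]) else exp(best$par[3])),
    tree = tr, key_columns = key_columns,
    convergence = list(code = best$convergence, restarts = restarts, seed = seed)
  ), class = "fixed_sites_fit")

  lrt <- likelihood_ratio_test(fit_A, fit_B, alpha = alpha)
  list(fit_A = fit_A, fit_B = fit_B, lrt = lrt)
}

#' @export
print.fixed_sites_fit <- function(x, ...) {
  cat("Fixed-sites model", sub("FS-", "", x$model), "\n")
  cat(sprintf("  lnL = %.4f (np = %d)\n", x$lnL, x$np))
  if (x$model == "FS-A")
    cat(sprintf("  omega = %.4f, kappa = %.3f\n", x$mle$omega, x$mle$kappa))
  else
    cat(sprintf("  omega_key = %.4f, omega_rest = %.4f, kappa = %.3f\n",
                x$mle$omega_key, x$mle$omega_rest, x$mle$kappa))
  invisible(x)
}
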