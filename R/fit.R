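## Maximum-likelihood fitting of codon site models (M0, M1a, M2a, M3, M7, M8)
## on a fixed tree topology, with branch lengths re-estimated by default.
## The classic modelling-function idiom: fit_site_model() returns a classed
## object with print/summary/coef/logLik/fitted/plot/simulate/anova methods.

## ---- internal plumbing -----------------------------------------------------

## Compress a codon alignment to unique column patterns.
## Returns list(states = n_tip x npat integer matrix (0 = gap), weights,
## pattern_of_column).
compress_patterns <- function(alignment, tip_order) {
  m <- alignment$codons[tip_order, , drop = FALSE]
  idx <- matrix(codon_index(m), nrow = nrow(m))
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  states <- idx[, match(uk, key), drop = FALSE]
  list(states = states, weights = tabulate(map, length(uk)), map = map)
}

## Per-class site log-likelihoods via the C++ pruning kernel.
class_logliks <- function(dat, blens, kappa, omegas, props) {
  tabs <- codon_tables()
  site_class_loglik_cpp(dat$edge, blens, dat$n_tip, dat$n_node, dat$states,
                        dat$pi, kappa, omegas, props,
                        tabs$pairs$i - 1L, tabs$pairs$j - 1L,
                        as.integer(tabs$pairs$transition),
                        as.integer(tabs$pairs$synonymous))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## Site-class structure for each model from unconstrained parameters.
## theta layout: [model params..., log kappa, log blens...]
model_npar <- function(model, K3 = 3) {
  switch(model, M0 = 1L, M1a = 2L, M2a = 4L, M3 = 2L * K3 - 1L,
         M7 = 2L, M8 = 4L, stop("unknown model: ", model))
}

## stick-breaking: unconstrained a (length K-1) -> simplex of length K
stick_break <- function(a) {
  p <- numeric(length(a) + 1)
  rem <- 1
  for (i in seq_along(a)) {
    p[i] <- rem * stats::plogis(a[i])
    rem <- rem - p[i]
  }
  p[length(p)] <- rem
  p
}
stick_break_inv <- function(p) {
  a <- numeric(length(p) - 1)
  rem <- 1
  for (i in seq_along(a)) {
    a[i] <- stats::qlogis(min(max(p[i] / rem, 1e-12), 1 - 1e-12))
    rem <- rem - p[i]
  }
  a
}

clamp_shape <- function(x) min(max(x, 5e-3), 99)

model_classes <- function(model, pars, K3 = 3, Kbeta = 10) {
  switch(model,
    M0 = list(props = 1, omegas = exp(pars[1])),
    M1a = {
      w0 <- stats::plogis(pars[1]); p0 <- stats::plogis(pars[2])
      list(props = c(p0, 1 - p0), omegas = c(w0, 1))
    },
    M2a = {
      w0 <- stats::plogis(pars[1]); w2 <- 1 + exp(pars[2])
      pr <- stick_break(pars[3:4])
      list(props = pr, omegas = c(w0, 1, w2))
    },
    M3 = {
      w <- exp(pars[seq_len(K3)])
      pr <- stick_break(pars[K3 + seq_len(K3 - 1)])
      list(props = pr, omegas = w)
    },
    M7 = {
      p <- clamp_shape(exp(pars[1])); q <- clamp_shape(exp(pars[2]))
      d <- discretize_beta(p, q, Kbeta)
      list(props = d$proportion, omegas = d$omega, beta = c(p = p, q = q))
    },
    M8 = {
      p <- clamp_shape(exp(pars[1])); q <- clamp_shape(exp(pars[2]))
      p0 <- stats::plogis(pars[3]); w10 <- 1 + exp(pars[4])
      d <- discretize_beta(p, q, Kbeta)
      list(props = c(p0 * d$proportion, 1 - p0),
           omegas = c(d$omega, w10), beta = c(p = p, q = q),
           positive = c(p10 = 1 - p0, omega10 = w10))
    })
}

default_init <- function(model, K3 = 3) {
  switch(model,
    M0 = log(0.4),
    M1a = c(stats::qlogis(0.2), stats::qlogis(0.7)),
    M2a = c(stats::qlogis(0.2), log(1), stick_break_inv(c(0.65, 0.3, 0.05))),
    M3 = c(log(c(0.05, 0.3, 1.2)), stick_break_inv(c(0.5, 0.35, 0.15)))[
      c(seq_len(K3), K3 + seq_len(K3 - 1))],
    M7 = c(log(0.5), log(1.5)),
    M8 = c(log(0.5), log(1.5), stats::qlogis(0.9), log(1)))
}

## Map a fitted null model's MLEs to an initial point for a nesting
## alternative (used to warm-start M2a from M1a and M8 from M7).
warm_start_pars <- function(fit, model) {
  if (is.null(fit)) return(NULL)
  from <- fit$model
  if (from == "M1a" && model == "M2a") {
    p <- fit$mle
    shrink <- 1 - 1e-3
    c(stats::qlogis(min(max(p$omegas[1], 1e-8), 1 - 1e-8)), log(0.05),
      stick_break_inv(c(p$props[1] * shrink, p$props[2] * shrink,
                        1 - shrink * (p$props[1] + p$props[2]))))
  } else if (from == "M7" && model == "M8") {
    c(log(fit$mle$beta["p"]), log(fit$mle$beta["q"]),
      stats::qlogis(1 - 1e-3), log(0.05))
  } else if (from == "M0" && model == "M3") {
    w <- fit$mle$omegas[1]
    c(log(pmax(c(w / 3, w, w * 3), 1e-6)), stick_break_inv(c(0.4, 0.4, 0.2)))
  } else NULL
}

## ---- the fitting function --------------------------------------------------

#' Fit a codon site model by maximum likelihood
#'
#' Fits one of the standard site-class codon models to a codon alignment on a
#' fixed tree topology: `M0` (one ratio), `M1a` (nearly neutral), `M2a`
#' (positive selection), `M3` (discrete classes), `M7` (beta), `M8`
#' (beta plus a positive class with omega >= 1). The likelihood is maximized
#' over kappa, branch lengths (unless `fix_blens`), and the model-specific
#' class parameters, using bounded quasi-Newton iterations on transformed
#' parameters (proportions via stick-breaking, rates via log) with optional
#' random restarts. Gap cells are treated as missing data.
#'
#' @param alignment A `codon_alignment`, at least 3 sequences.
#' @param tree An `ape::phylo` over the alignment labels. Its branch lengths
#'   seed the optimizer (default 0.1 where absent).
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`.
#' @param codon_freq Frequency scheme passed to [codon_frequencies()], or a
#'   numeric 61-vector.
#' @param fix_blens If `TRUE`, branch lengths are fixed at the tree's values.
#' @param restarts Number of jittered restarts after the first start
#'   (default 2, i.e. 3 optimizer runs in total).
#' @param init Optional warm start: a `site_model_fit` of a nested null model,
#'   or a numeric vector of model parameters on the transformed scale.
#' @param K3 Number of classes for M3.
#' @param seed Seed for restart jitter (recorded in the fit).
#' @param control Passed to [stats::nlminb()] control (defaults set rel.tol
#'   `1e-10`).
#' @return A `site_model_fit` object: maximized `lnL`, MLEs (`kappa`, class
#'   `props`/`omegas`, beta shapes where relevant), the tree with ML branch
#'   lengths, per-column NEB posteriors and posterior-mean omega, the free
#'   parameter count `np`, and convergence diagnostics.
#' @export
fit_site_model <- function(alignment, tree, model = c("M0", "M1a", "M2a", "M3", "M7", "M8"),
                           codon_freq = "F3x4", fix_blens = FALSE, restarts = 2,
                           init = NULL, K3 = 3, seed = 1, control = list()) {
  model <- match.arg(model)
  validate_codon_alignment(alignment)
  dat <- prepare_fit_data(alignment, tree, codon_freq)
  npar_m <- model_npar(model, K3)

  bl0 <- dat$blens0
  theta_model0 <- if (inherits(init, "site_model_fit")) {
    ws <- warm_start_pars(init, model)
    if (!is.null(init$tree$edge.length) &&
        length(init$tree$edge.length) == length(bl0))
      bl0 <- pmax(init$tree$edge.length, 1e-6)
    if (is.null(ws)) default_init(model, K3) else ws
  } else if (is.numeric(init)) init else default_init(model, K3)
  kappa0 <- if (inherits(init, "site_model_fit")) init$mle$kappa else 2

  pack <- function(pm, k, bl) {
    if (fix_blens) c(pm, log(k)) else c(pm, log(k), log(bl))
  }
  unpack <- function(theta) {
    pm <- theta[seq_len(npar_m)]
    k <- exp(theta[npar_m + 1])
    bl <- if (fix_blens) bl0 else exp(theta[npar_m + 1 + seq_along(bl0)])
    list(pm = pm, kappa = k, blens = bl)
  }
  negll <- function(theta) {
    u <- unpack(theta)
    if (u$kappa > 200 || any(u$blens > 50)) return(1e10)
    cls <- model_classes(model, u$pm, K3)
    ll <- class_logliks(dat, u$blens, u$kappa, cls$omegas, cls$props)
    v <- logsumexp_rows(sweep(ll, 2, log(cls$props), "+"))
    val <- -sum(dat$weights * v)
    if (!is.finite(val)) 1e10 else val
  }

  ctrl <- utils::modifyList(list(rel.tol = 1e-10, eval.max = 5000, iter.max = 1000),
                            control)
  theta0 <- pack(theta_model0, kappa0, bl0)
  best <- NULL
  n_runs <- restarts + 1
  for (r in seq_len(n_runs)) {
    th <- theta0
    if (r > 1) {
      set.seed(seed + r)
      th <- th + stats::rnorm(length(th), 0, 0.3)
    }
    opt <- tryCatch(stats::nlminb(th, negll, control = ctrl),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best)) stop("optimization failed for model ", model)
  ## polish: a short second run from the optimum at tighter tolerance guards
  ## against premature convergence (matters for nested-model comparisons)
  polish <- tryCatch(stats::nlminb(best$par, negll,
                                   control = utils::modifyList(ctrl, list(
                                     rel.tol = ctrl$rel.tol * 1e-2, eval.max = 500,
                                     iter.max = 100))),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$objective < best$objective) best <- polish

  u <- unpack(best$par)
  cls <- model_classes(model, u$pm, K3)
  ll <- class_logliks(dat, u$blens, u$kappa, cls$omegas, cls$props)
  lw <- sweep(ll, 2, log(cls$props), "+")
  site_ll <- logsumexp_rows(lw)
  post_pat <- exp(lw - site_ll)                 # patterns x K
  posteriors <- post_pat[dat$map, , drop = FALSE]
  neb_omega <- as.vector(posteriors %*% cls$omegas)

  tr <- dat$tree
  tr$edge.length <- u$blens
  np <- npar_m + 1L + if (fix_blens) 0L else length(bl0)

  structure(list(
    model = model, lnL = -best$objective,
    mle = list(kappa = u$kappa, props = cls$props, omegas = cls$omegas,
               beta = cls$beta, positive = cls$positive),
    tree = tr, pi = dat$pi, codon_freq = dat$freq_scheme,
    posteriors = posteriors, neb_omega = neb_omega,
    site_logliks = ll, weights = dat$weights, map = dat$map,
    np = np, n_col = alignment$column_count, labels = alignment$labels,
    convergence = list(code = best$convergence, message = best$message,
                       iterations = best$iterations, restarts = restarts,
                       seed = seed),
    call = match.call()
  ), class = "site_model_fit")
}

## Shared data preparation: tree checks, postorder edges, pattern compression,
## equilibrium frequencies.
prepare_fit_data <- function(alignment, tree, codon_freq) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  if (!setequal(tree$tip.label, alignment$labels))
    stop("tree tip labels must match alignment labels")
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  pat <- compress_patterns(alignment, tree$tip.label)
  pi61 <- if (is.numeric(codon_freq)) {
    stopifnot(length(codon_freq) == 61)
    codon_freq / sum(codon_freq)
  } else codon_frequencies(alignment, codon_freq)
  bl0 <- tree$edge.length
  if (is.null(bl0)) bl0 <- rep(0.1, nrow(tree$edge))
  bl0 <- pmax(bl0, 1e-6)
  list(tree = tree, edge = tree$edge, blens0 = bl0,
       n_tip = length(tree$tip.label), n_node = tree$Nnode,
       states = pat$states, weights = pat$weights, map = pat$map,
       pi = pi61, freq_scheme = if (is.character(codon_freq)) codon_freq else "custom")
}

## ---- methods ---------------------------------------------------------------

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Codon site model ", x$model, " (", x$codon_freq, " frequencies)\n", sep = "")
  cat(sprintf("  lnL = %.4f  (np = %d, %d sequences, %d codon columns)\n",
              x$lnL, x$np, length(x$labels), x$n_col))
  cat(sprintf("  kappa = %.3f\n", x$mle$kappa))
  cls <- data.frame(proportion = round(x$mle$props, 4),
                    omega = round(x$mle$omegas, 4))
  print(cls, row.names = FALSE)
  invisible(x)
}

#' @export
summary.site_model_fit <- function(object, threshold = 0.95, ...) {
  rep <- neb_site_report(object, threshold = threshold)
  out <- list(fit = object, report = rep,
              n_positive = sum(rep$call == "Positive"),
              mean_omega = mean(object$neb_omega))
  class(out) <- "summary.site_model_fit"
  out
}

#' @export
print.summary.site_model_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean NEB omega = %.4f; columns called Positive: %d\n",
              x$mean_omega, x$n_positive))
  pos <- x$report[x$report$P_positive > 0.5, , drop = FALSE]
  if (nrow(pos)) {
    cat("  columns with P(omega > 1) > 0.5:\n")
    print(utils::head(pos, 12), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.site_model_fit <- function(object, ...) {
  m <- object$mle
  out <- c(kappa = m$kappa)
  if (!is.null(m$beta)) out <- c(out, p = unname(m$beta["p"]), q = unname(m$beta["q"]))
  if (object$model %in% c("M0", "M1a", "M2a", "M3")) {
    w <- m$omegas; names(w) <- paste0("omega", seq_along(w) - 1)
    p <- m$props; names(p) <- paste0("p", seq_along(p) - 1)
    out <- c(out, w, p[-length(p)])
  }
  if (!is.null(m$positive))
    out <- c(out, p_pos = unname(m$positive["p10"]),
             omega_pos = unname(m$positive["omega10"]))
  out
}

#' @export
logLik.site_model_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}

#' Per-column NEB posterior-mean omega
#' @param object A `site_model_fit`.
#' @param ... Unused.
#' @export
fitted.site_model_fit <- function(object, ...) object$neb_omega

#' @export
plot.site_model_fit <- function(x, key_columns = NULL, ...) {
  graphics::plot(seq_len(x$n_col), x$neb_omega, type = "h", log = "y",
                 xlab = "MSA codon column", ylab = "NEB omega",
                 main = paste("Site omega profile,", x$model), ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  if (!is.null(key_columns))
    graphics::points(key_columns, x$neb_omega[key_columns], pch = 19, col = "red")
  invisible(x)
}

#' Simulate codon alignments from a fitted site model
#' @param object A `site_model_fit`.
#' @param nsim Number of alignments.
#' @param seed Optional seed.
#' @param n_codons Number of codon columns (defaults to the fitted data's).
#' @param ... Unused.
#' @return A list of `codon_alignment` objects with attribute `"site_class"`.
#' @export
simulate.site_model_fit <- function(object, nsim = 1, seed = NULL,
                                    n_codons = object$n_col, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_codon_alignment(tree = object$tree, n_codons = n_codons,
                             kappa = object$mle$kappa, pi = object$pi,
                             props = object$mle$props, omegas = object$mle$omegas))
}

#' Likelihood ratio tests between nested fitted site models
#'
#' @param object The null-model fit.
#' @param ... The alternative-model fit (one `site_model_fit`).
#' @param alpha Significance level for the tenable-model call.
#' @export
anova.site_model_fit <- function(object, ..., alpha = 0.05) {
  alt <- list(...)[[1]]
  likelihood_ratio_test(object, alt, alpha = alpha)
}

#' Likelihood ratio test between nested codon model fits
#'
#' `Delta = lnL_alt - lnL_null`, `LR = 2 Delta`, with the p-value from the
#' chi-square upper tail. The alternative is called tenable when
#' `p < alpha`, otherwise the null.
#'
#' @param fit_null,fit_alt `site_model_fit` (or fixed-sites) objects.
#' @param df Degrees of freedom; defaults to the difference in free parameter
#'   counts.
#' @param alpha Significance level (default 0.05).
#' @return An `lrt` object: `Delta`, `LR`, `df`, `p_value`, `tenable`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt, df = NULL, alpha = 0.05) {
  if (is.null(df)) df <- fit_alt$np - fit_null$np
  if (df < 1) stop("models not nested: df < 1")
  delta <- fit_alt$lnL - fit_null$lnL
  if (delta < -1e-4)
    stop(sprintf("optimizer failure: lnL(alt) - lnL(null) = %.6f < 0", delta))
  delta <- max(delta, 0)
  p <- stats::pchisq(2 * delta, df = df, lower.tail = FALSE)
  structure(list(Delta = delta, LR = 2 * delta, df = df, p_value = p,
                 tenable = if (p < alpha) fit_alt$model else fit_null$model,
                 null = fit_null$model, alt = fit_alt$model, alpha = alpha),
            class = "lrt")
}

#' @export
print.lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: Delta = %.4f, LR = 2 Delta = %.4f, df = %d, p = %.3g\n",
              x$alt, x$null, x$Delta, x$LR, x$df, x$p_value))
  cat("  tenable model at alpha =", x$alpha, ":", x$tenable, "\n")
  invisible(x)
}

#' Naive empirical Bayes per-site report
#'
#' Posterior class memberships at the MLEs give, per alignment column, the
#' posterior probability that omega > 1 and the posterior-mean (NEB) omega.
#' Columns whose P(omega > 1) exceeds `threshold` are called `"Positive"`.
#'
#' @param fit A `site_model_fit`.
#' @param position_map Optional data.frame from [read_position_map()] to add
#'   Ballesteros-Weinstein labels and key flags.
#' @param threshold Posterior probability for a Positive call (default 0.95).
#' @return data.frame with `column`, optional `bw_index`/`key`, `P_positive`,
#'   `neb_omega`, `call`.
#' @export
neb_site_report <- function(fit, position_map = NULL, threshold = 0.95) {
  stopifnot(inherits(fit, "site_model_fit"))
  pos_classes <- fit$mle$omegas > 1
  P_pos <- as.vector(fit$posteriors[, pos_classes, drop = FALSE] %*%
                       rep(1, sum(pos_classes)))
  out <- data.frame(column = seq_len(fit$n_col),
                    P_positive = P_pos, neb_omega = fit$neb_omega,
                    call = ifelse(P_pos > threshold, "Positive",
                                  ifelse(fit$neb_omega < 1 & P_pos < 1 - threshold,
                                         "Negative", "-")),
                    stringsAsFactors = FALSE)
  if (!is.null(position_map)) {
    i <- match(out$column, position_map$column_index)
    out$bw_index <- position_map$bw_index[i]
    out$key <- position_map$is_key[i]
    out <- out[, c("column", "bw_index", "key", "P_positive", "neb_omega", "call")]
  }
  out
}
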