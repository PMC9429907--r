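# Flow-cytometry spore gating.
#
# Events stained with SYBR green separate into vegetative cells (dye enters,
# high fluorescence) and spores (dye excluded, low fluorescence). The gating
# chain is: asinh transform of scatter and fluorescence intensities ->
# singlet gate on (FSC-H, FSC-A) -> noise gate on the low tail of FSC-A ->
# two-component Gaussian mixture over (FSC-A, FL-A) fitted on non-induced
# control samples per strain and run, then applied to every sample of that
# strain; the component with the lower mean fluorescence is the spore
# population.

#' Hyperbolic arcsine transform of intensity channels
#'
#' @param events Data frame of per-event intensities.
#' @param cofactor Positive scale divisor applied before `asinh`.
#' @param channels Columns to transform (default the scatter height/area and
#'   fluorescence area channels).
#' @return The events with transformed channels (attribute
#'   `asinh_cofactor` records the cofactor).
#' @export
asinh_transform <- function(events, cofactor = 1,
                            channels = c("fsc_h", "fsc_a", "fl_a")) {
  if (cofactor <= 0) stop("asinh_transform: cofactor must be > 0")
  channels <- intersect(channels, names(events))
  for (ch in channels) {
    x <- events[[ch]]
    if (any(!is.finite(x))) stop("asinh_transform: non-finite values in ", ch)
    events[[ch]] <- asinh(x / cofactor)
  }
  attr(events, "asinh_cofactor") <- cofactor
  events
}

# Theil-Sen slope on (x, y): median pairwise slope over an evenly spaced
# subsample (deterministic), robust to a minority of doublets
.theil_sen <- function(x, y, max_points = 400L) {
  n <- length(x)
  idx <- if (n > max_points) {
    o <- order(x)
    o[unique(round(seq(1, n, length.out = max_points)))]
  } else seq_len(n)
  xs <- x[idx]; ys <- y[idx]
  m <- length(xs)
  i <- rep(seq_len(m - 1), times = (m - 1):1)
  j <- sequence((m - 1):1) + i
  dx <- xs[j] - xs[i]
  ok <- abs(dx) > .Machine$double.eps
  slope <- stats::median((ys[j] - ys[i])[ok] / dx[ok])
  intercept <- stats::median(y - slope * x)
  c(slope = slope, intercept = intercept)
}

#' Singlet gate on transformed FSC height versus area
#'
#' Doublets carry roughly doubled area at unchanged height, so they fall off
#' the singlet height~area line. A robust (Theil--Sen) line is fitted to
#' transformed FSC-H on FSC-A and events within `k` robust scale units
#' (median absolute deviation) of the line are kept.
#'
#' @param events Transformed events with `fsc_h`, `fsc_a`.
#' @param k Band half-width in robust scale units (default 2.5).
#' @param min_events Minimum events for a stable fit (default 50).
#' @return Logical mask, TRUE for singlets.
#' @export
singlet_gate <- function(events, k = 2.5, min_events = 50L) {
  n <- nrow(events)
  if (n < min_events)
    stop("singlet_gate: need at least ", min_events, " events")
  fit <- .theil_sen(events$fsc_a, events$fsc_h)
  res <- events$fsc_h - (fit["slope"] * events$fsc_a + fit["intercept"])
  scale <- stats::mad(res)
  if (scale == 0) scale <- stats::sd(res)
  if (is.infinite(k)) return(rep(TRUE, n))
  abs(res) <= k * scale
}

#' Noise gate on the low tail of transformed FSC area
#'
#' Sub-cellular noise events sit in a low-scatter mode. A kernel density
#' estimate (Silverman bandwidth) of transformed FSC-A is scanned for local
#' minima below the global mode; the threshold is placed at the deepest such
#' minimum and events above it are kept. If the density has no minimum below
#' the mode the gate falls back to dropping the `fallback_quantile` lowest
#' fraction (set `fallback_quantile = NULL` to retain everything with a
#' warning instead).
#'
#' @param events Transformed events with `fsc_a`.
#' @param fallback_quantile Low quantile dropped when no density minimum
#'   exists (default 0.005).
#' @return Logical mask, TRUE for retained events.
#' @export
noise_gate <- function(events, fallback_quantile = 0.005) {
  x <- events$fsc_a
  d <- stats::density(x, bw = "nrd0")
  mode_i <- which.max(d$y)
  y <- d$y
  is_min <- c(FALSE, y[2:(length(y) - 1)] < y[1:(length(y) - 2)] &
                     y[2:(length(y) - 1)] <= y[3:length(y)], FALSE)
  cand <- which(is_min & seq_along(y) < mode_i)
  if (length(cand)) {
    thr <- d$x[cand[which.min(y[cand])]]
    return(x >= thr)
  }
  if (is.null(fallback_quantile)) {
    warning("noise_gate: no density minimum below the mode; retaining all events")
    return(rep(TRUE, length(x)))
  }
  x >= stats::quantile(x, fallback_quantile, names = FALSE)
}

# log density of rows of X under N(mu, Sigma)
.dmvnorm_log <- function(X, mu, Sigma) {
  L <- chol(Sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - ncol(X) / 2 * log(2 * pi)
}

# one EM run from given responsibilities; returns NULL on failure
.em_gmm2 <- function(X, resp, max_iter = 500L, tol = 1e-8) {
  n <- nrow(X)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < 2)) return(NULL)
    w <- nk / n
    mus <- lapply(1:2, function(k) colSums(X * resp[, k]) / nk[k])
    covs <- lapply(1:2, function(k) {
      Xc <- sweep(X, 2, mus[[k]])
      S <- crossprod(Xc * resp[, k], Xc) / nk[k]
      S + diag(1e-8, ncol(X))
    })
    logd <- tryCatch(
      vapply(1:2, function(k)
        log(w[k]) + .dmvnorm_log(X, mus[[k]], covs[[k]]), numeric(n)),
      error = function(e) NULL)
    if (is.null(logd)) return(NULL)
    m <- pmax(logd[, 1], logd[, 2])
    lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = w, means = mus, covs = covs, loglik = ll, resp = resp,
       iterations = iter)
}

#' Fit the two-population spore/vegetative Gaussian mixture
#'
#' EM fit of a two-component full-covariance bivariate Gaussian mixture on
#' transformed (FSC-A, FL-A), trained on gated non-induced control events of
#' one strain on one experimental run. Several seeded restarts are run
#' (k-means initialisations) and the best log-likelihood kept. The component
#' with the lower mean fluorescence is labelled `spore`, the higher
#' `vegetative`.
#'
#' @param events Gated, transformed control events with `fsc_a`, `fl_a`.
#' @param strain,run Training context recorded on the model.
#' @param restarts Number of seeded EM restarts (default 5).
#' @param seed Base seed for the restarts.
#' @param min_events Minimum training events (default 1000).
#' @return An object of class `spore_mixture`.
#' @export
fit_spore_mixture <- function(events, strain = "unknown", run = "unknown",
                              restarts = 5L, seed = 1L, min_events = 1000L) {
  X <- cbind(fsc_a = events$fsc_a, fl_a = events$fl_a)
  if (nrow(X) < min_events)
    stop("fit_spore_mixture: need at least ", min_events, " gated events")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r - 1L, {
      km <- tryCatch(stats::kmeans(X, centers = 2L, nstart = 1L),
                     error = function(e) NULL)
      if (is.null(km)) return(NULL)
      resp <- cbind(km$cluster == 1L, km$cluster == 2L) * 1
      .em_gmm2(X, resp)
    })
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("fit_spore_mixture: EM failed to converge in all restarts")
  if (any(best$weights < 0.001))
    warning("fit_spore_mixture: degenerate split (component weight < 0.1%)")
  fl_means <- vapply(best$means, `[[`, 0, "fl_a")
  spore_k <- which.min(fl_means)
  ord <- c(spore_k, setdiff(1:2, spore_k))
  model <- list(weights = best$weights[ord],
                means = best$means[ord],
                covs = best$covs[ord],
                labels = c("spore", "vegetative"),
                loglik = best$loglik,
                strain = strain, run = run, n_train = nrow(X))
  class(model) <- "spore_mixture"
  model
}

#' @export
print.spore_mixture <- function(x, ...) {
  cat(sprintf("Spore/vegetative Gaussian mixture (strain %s, run %s; n = %d)\n",
              x$strain, x$run, x$n_train))
  for (k in 1:2)
    cat(sprintf("  %-10s weight %.3f, mean (FSC-A %.2f, FL-A %.2f)\n",
                x$labels[k], x$weights[k],
                x$means[[k]]["fsc_a"], x$means[[k]]["fl_a"]))
  invisible(x)
}

#' Posterior spore probability per event
#'
#' @param object A `spore_mixture`.
#' @param events Gated, transformed events with `fsc_a`, `fl_a`.
#' @param ... Unused.
#' @return Numeric vector of posterior probabilities of the spore component.
#' @export
predict.spore_mixture <- function(object, events, ...) {
  X <- cbind(fsc_a = events$fsc_a, fl_a = events$fl_a)
  logd <- vapply(1:2, function(k)
    log(object$weights[k]) + .dmvnorm_log(X, object$means[[k]],
                                          object$covs[[k]]),
    numeric(nrow(X)))
  logd <- matrix(logd, ncol = 2)
  1 / (1 + exp(logd[, 2] - logd[, 1]))
}

#' Classify gated events as spores or vegetative cells
#'
#' Maximum-posterior assignment under a trained mixture. The model must have
#' been trained on the same strain and run unless `override = TRUE`.
#'
#' @param model A [fit_spore_mixture()] model.
#' @param events Gated, transformed events.
#' @param strain,run Context of the events (checked against the model).
#' @param override Skip the context check.
#' @return A `spore_count` list: `n_spores`, `n_vegetative`, `n_total_gated`,
#'   `pct_spores`.
#' @export
classify_events <- function(model, events, strain = model$strain,
                            run = model$run, override = FALSE) {
  stopifnot(inherits(model, "spore_mixture"))
  if (!override && (!identical(strain, model$strain) ||
                    !identical(run, model$run)))
    stop("classify_events: model trained on strain '", model$strain,
         "' run '", model$run, "'; pass override = TRUE to apply anyway")
  if (nrow(events) == 0) stop("classify_events: empty event set")
  post <- predict(model, events)
  n_sp <- sum(post > 0.5)
  out <- list(n_spores = n_sp, n_vegetative = nrow(events) - n_sp,
              n_total_gated = nrow(events),
              pct_spores = 100 * n_sp / nrow(events))
  class(out) <- "spore_count"
  out
}

#' Spore yield of an induced culture relative to its paired control
#'
#' @param induced,control `spore_count` objects (or lists with `pct_spores`).
#' @return Ratio of percent spores, induced / control.
#' @export
spore_yield <- function(induced, control) {
  if (control$pct_spores <= 0)
    stop("spore_yield: control percent spores must be > 0")
  induced$pct_spores / control$pct_spores
}

#' Compare per-clone spore yields against the empty-vector control
#'
#' Welch test per strain versus the empty-vector yields, with p values
#' adjusted across strains.
#'
#' @param strain_yields Named list of numeric per-clone yield vectors.
#' @param empty_vector_yields Numeric yield vector of the negative control.
#' @param adjust Adjustment method passed to [adjust_pvalues()].
#' @return Data frame with per-strain `t`, `df`, `p`, `p_adj`, means and n.
#' @export
compare_yields <- function(strain_yields, empty_vector_yields,
                           adjust = c("holm", "bh", "by")) {
  adjust <- match.arg(adjust)
  rows <- lapply(names(strain_yields), function(s) {
    w <- welch_t_test(strain_yields[[s]], empty_vector_yields)
    data.frame(strain = s, t = w$t, df = w$df, p = w$p,
               mean_yield = w$mean_a, mean_control = w$mean_b,
               n = w$n_a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Full gating chain for one sample
#'
#' asinh transform, singlet gate, then noise gate; returns the retained,
#' transformed events.
#'
#' @param events Raw events with `fsc_h`, `fsc_a`, `fl_a`.
#' @param cofactor asinh cofactor.
#' @param k Singlet band half-width.
#' @param fallback_quantile Noise-gate fallback quantile.
#' @param min_events Minimum raw events per sample (default 500).
#' @return Gated transformed events; attribute `gate_stats` records the
#'   number retained at each step.
#' @export
gate_events <- function(events, cofactor = 1, k = 2.5,
                        fallback_quantile = 0.005, min_events = 500L) {
  if (nrow(events) < min_events)
    stop("gate_events: need at least ", min_events, " events")
  tr <- asinh_transform(events, cofactor = cofactor)
  singlet <- singlet_gate(tr, k = k)
  tr1 <- tr[singlet, , drop = FALSE]
  kept <- noise_gate(tr1, fallback_quantile = fallback_quantile)
  out <- tr1[kept, , drop = FALSE]
  attr(out, "gate_stats") <- c(n_input = nrow(events),
                               n_singlet = nrow(tr1), n_gated = nrow(out))
  out
}

#' Gate, fit on the control, and count spores in paired samples
#'
#' Runs the full pipeline for one induced/control pair of one strain and run:
#' both samples are gated, the mixture is trained on the control, both are
#' classified, and the spore yield is computed.
#'
#' @param induced_events,control_events Raw event tables.
#' @param strain,run Training context.
#' @param ... Passed to [gate_events()] and [fit_spore_mixture()].
#' @return List with `model`, `induced` and `control` spore counts, `yield`.
#' @export
spore_pipeline <- function(induced_events, control_events,
                           strain = "unknown", run = "unknown", ...) {
  dots <- list(...)
  gate_args <- dots[intersect(names(dots),
                              c("cofactor", "k", "fallback_quantile",
                                "min_events"))]
  fit_args <- dots[intersect(names(dots), c("restarts", "seed"))]
  g_ctrl <- do.call(gate_events, c(list(control_events), gate_args))
  g_ind <- do.call(gate_events, c(list(induced_events), gate_args))
  model <- do.call(fit_spore_mixture,
                   c(list(g_ctrl, strain = strain, run = run), fit_args))
  ctrl <- classify_events(model, g_ctrl)
  ind <- classify_events(model, g_ind)
  list(model = model, induced = ind, control = ctrl,
       yield = spore_yield(ind, ctrl))
}
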