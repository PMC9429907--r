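# Flow-cytometry gating chain and spore/vegetative mixture classification.

test_that("asinh transform is exact and order preserving", {
  ev <- data.frame(fsc_h = c(0, 1, 10), fsc_a = c(0, 1, 10),
                   fl_a = c(0, 1, 10))
  tr <- asinh_transform(ev, cofactor = 1)
  expect_equal(tr$fl_a, asinh(c(0, 1, 10)))
  expect_equal(tr$fl_a[2], 0.881373587, tolerance = 1e-8)
  set.seed(3)
  x <- rexp(100, 1 / 500)
  tr2 <- asinh_transform(data.frame(fl_a = x), cofactor = 150,
                         channels = "fl_a")
  expect_equal(order(tr2$fl_a), order(x))
  expect_error(asinh_transform(data.frame(fl_a = c(1, Inf))), "non-finite")
  expect_error(asinh_transform(ev, cofactor = 0), "> 0")
})

test_that("singlet gate keeps the singlet line and rejects planted doublets", {
  g <- gen_flow_events(8000, 0.3, doublet_fraction = 0.05,
                       noise_fraction = 0, seed = 17)
  tr <- asinh_transform(g$events)
  mask <- singlet_gate(tr)
  doublet <- g$truth$class == "doublet"
  expect_gte(mean(!mask[doublet]), 0.95)       # doublets removed
  expect_gte(mean(mask[!doublet]), 0.97)       # singlets kept

  pure <- gen_flow_events(5000, 0.3, doublet_fraction = 0,
                          noise_fraction = 0, seed = 18)
  trp <- asinh_transform(pure$events)
  # a Gaussian residual band at k = 2.5 robust scales keeps ~98.8% in theory
  expect_gte(mean(singlet_gate(trp)), 0.98)
  expect_true(all(singlet_gate(trp, k = Inf)))
  expect_error(singlet_gate(trp[1:10, ]), "at least")
})

test_that("noise gate thresholds between the noise mode and the cell modes", {
  g <- gen_flow_events(10000, 0.3, doublet_fraction = 0,
                       noise_fraction = 0.05, seed = 23)
  tr <- asinh_transform(g$events)
  mask <- noise_gate(tr)
  noise <- g$truth$class == "noise"
  expect_gte(mean(!mask[noise]), 0.95)
  expect_gte(mean(mask[!noise]), 0.99)

  # a single tight mode falls back to the low quantile
  tight <- data.frame(fsc_a = rnorm(5000, 5, 0.2))
  expect_gte(mean(noise_gate(tight)), 0.995)
  expect_warning(m <- noise_gate(tight, fallback_quantile = NULL),
                 "retaining all")
  expect_true(all(m))

  # translation equivariance: shifting intensities shifts the threshold
  shifted <- tr; shifted$fsc_a <- shifted$fsc_a + 2.5
  expect_equal(noise_gate(shifted), mask)
})

test_that("mixture fit recovers planted weights and labels by fluorescence", {
  g <- gen_flow_events(20000, 0.3, doublet_fraction = 0, noise_fraction = 0,
                       seed = 29)
  tr <- asinh_transform(g$events)
  m <- fit_spore_mixture(tr, strain = "wt", run = "r1", seed = 1)
  expect_equal(m$labels, c("spore", "vegetative"))
  expect_lt(m$means[[1]]["fl_a"], m$means[[2]]["fl_a"])
  expect_lt(abs(m$weights[1] - 0.30), 0.02)
  expect_lt(abs(m$weights[2] - 0.70), 0.02)

  # self-classification recovers the spore weight
  sc <- classify_events(m, tr)
  expect_lt(abs(sc$pct_spores / 100 - m$weights[1]), 0.02)
  expect_equal(sc$n_spores + sc$n_vegetative, sc$n_total_gated)

  # an event at a component mean is assigned to that component
  at_mean <- data.frame(fsc_a = m$means[[1]]["fsc_a"],
                        fl_a = m$means[[1]]["fl_a"])
  expect_gt(predict(m, at_mean), 0.5)

  expect_error(fit_spore_mixture(tr[1:100, ]), "at least")
  expect_error(classify_events(m, tr, strain = "other"), "override")
  expect_error(classify_events(m, tr[0, ]), "empty")
})

test_that("mixture parameters agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  g <- gen_flow_events(10000, 0.25, doublet_fraction = 0, noise_fraction = 0,
                       seed = 31)
  tr <- asinh_transform(g$events)
  m <- fit_spore_mixture(tr, seed = 1)
  mc <- mclust::Mclust(cbind(tr$fsc_a, tr$fl_a), G = 2, modelNames = "VVV",
                       verbose = FALSE)
  w_ref <- sort(mc$parameters$pro)
  expect_equal(sort(m$weights), w_ref, tolerance = 0.01)
  mu_ref <- mc$parameters$mean[, order(mc$parameters$mean[2, ])]
  expect_equal(unname(m$means[[1]]), unname(mu_ref[, 1]), tolerance = 0.05)
  expect_equal(unname(m$means[[2]]), unname(mu_ref[, 2]), tolerance = 0.05)
})

test_that("end-to-end recovery of planted spore fractions with artefacts", {
  for (f in c(0.05, 0.70)) {
    g <- gen_flow_events(12000, f, doublet_fraction = 0.05,
                         noise_fraction = 0.05, seed = round(1000 * f))
    gated <- gate_events(g$events)
    m <- fit_spore_mixture(gated, seed = 1)
    sc <- classify_events(m, gated)
    expect_lt(abs(sc$pct_spores / 100 - f), 0.02)
  }
})

test_that("pipeline output is invariant to event order and monotone in f", {
  g <- gen_flow_events(8000, 0.4, seed = 37)
  run <- function(ev) {
    gated <- gate_events(ev)
    classify_events(fit_spore_mixture(gated, seed = 1), gated)$pct_spores
  }
  p1 <- run(g$events)
  p2 <- run(g$events[rev(seq_len(nrow(g$events))), ])
  expect_equal(p1, p2, tolerance = 1e-6)

  fracs <- c(0.1, 0.3, 0.5, 0.7)
  est <- vapply(fracs, function(f)
    run(gen_flow_events(8000, f, seed = 41)$events), 0)
  expect_true(all(diff(est) > 0))
})

test_that("spore yield ratios and the clone-level Welch comparison", {
  a <- list(pct_spores = 10); b <- list(pct_spores = 20)
  expect_equal(spore_yield(a, b), 0.5)
  expect_equal(spore_yield(b, b), 1.0)
  expect_error(spore_yield(a, list(pct_spores = 0)), "> 0")

  yields <- list(sigF = c(0.1, 0.15, 0.2, 0.12),
                 g120 = c(0.9, 1.1, 1.0, 0.95))
  ev <- c(1.0, 1.05, 0.95, 1.02)
  res <- compare_yields(yields, ev, adjust = "holm")
  expect_equal(res$p_adj, oracle_holm(res$p), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_lt(res$p_adj[res$strain == "sigF"], 0.05)

  same <- compare_yields(list(x = ev), ev)
  expect_equal(same$p, 1)
})

test_that("planted yield is recovered from paired induced/control samples", {
  ctrl <- gen_flow_events(12000, 0.2, seed = 51, treatment = "control")
  ind <- gen_flow_events(12000, 0.1, seed = 52, treatment = "induced")
  res <- spore_pipeline(ind$events, ctrl$events, strain = "wt", run = "r1",
                        seed = 1)
  expect_lt(abs(res$yield - 0.5), 0.05)
  # a sample paired with itself has yield exactly 1
  expect_equal(spore_yield(res$control, res$control), 1)
})
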