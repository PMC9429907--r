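# Seeded synthetic-data generators.
#
# Each generator emulates the statistical structure of one pipeline input and
# returns the data together with a truth sidecar sufficient to score the
# corresponding stage. All generators are deterministic under a fixed seed
# and leave the caller's RNG state untouched.

#' Generate a homology hit table with planted family labels
#'
#' Every protein receives a hit to its planted (non-general) family with
#' E-value drawn log-uniformly in \[1e-40, 1e-10\]; decoy hits to other
#' non-general families are at least `evalue_margin` times larger; with
#' probability `general_hit_rate` an umbrella-family hit smaller than all
#' others is added, so the best raw hit is general and the fallback rule must
#' fire to recover the planted label.
#'
#' @param n_proteins Number of proteins.
#' @param catalog A [family_catalog()]; needs >= 2 non-general families.
#' @param evalue_margin Decoy E-value inflation factor (> 1).
#' @param general_hit_rate Probability of planting a winning general hit.
#' @param n_decoys Decoy hits per protein.
#' @param seed RNG seed.
#' @return List with `hits` (data frame `protein_id`, `family_id`, `evalue`,
#'   `score`) and `truth` (`protein_id`, `planted_family`,
#'   `general_planted`).
#' @export
gen_hmm_hits <- function(n_proteins, catalog = default_family_catalog(),
                         evalue_margin = 10, general_hit_rate = 0,
                         n_decoys = 2L, seed = 1L) {
  if (evalue_margin <= 1) stop("gen_hmm_hits: evalue_margin must be > 1")
  nong <- catalog$family_id[!catalog$is_general]
  gen <- catalog$family_id[catalog$is_general]
  if (length(nong) < 2) stop("gen_hmm_hits: need >= 2 non-general families")
  with_seed(seed, {
    prot <- sprintf("prot%04d", seq_len(n_proteins))
    planted <- sample(nong, n_proteins, replace = TRUE)
    ev_planted <- 10^stats::runif(n_proteins, -40, -10)
    general_planted <- stats::runif(n_proteins) < general_hit_rate &
      length(gen) > 0
    rows <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      decoy_fams <- sample(setdiff(nong, planted[i]),
                           min(n_decoys, length(nong) - 1))
      ev_decoy <- ev_planted[i] * evalue_margin * 10^stats::runif(length(decoy_fams), 0, 3)
      fam <- c(planted[i], decoy_fams)
      ev <- c(ev_planted[i], ev_decoy)
      if (general_planted[i]) {
        fam <- c(fam, sample(gen, 1))
        ev <- c(ev, ev_planted[i] * 10^-stats::runif(1, 1, 3))
      }
      rows[[i]] <- data.frame(protein_id = prot[i], family_id = fam,
                              evalue = ev, score = -log10(ev) * 2,
                              stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    hits <- hits[sample(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    list(hits = hits,
         truth = data.frame(protein_id = prot, planted_family = planted,
                            general_planted = general_planted,
                            stringsAsFactors = FALSE))
  })
}

# random binary newick over prebuilt unit strings, spanning pair on opposite
# sides of the subtree root so the units' MRCA is the subtree root
.random_subtree <- function(units, span_pair = NULL) {
  bl <- function() stats::runif(1, 0.05, 1)
  join <- function(a, b) sprintf("(%s:%.4f,%s:%.4f)", a, bl(), b, bl())
  build <- function(u) {
    while (length(u) > 1) {
      i <- sample(length(u), 2)
      u <- c(u[-i], join(u[i[1]], u[i[2]]))
    }
    u
  }
  if (is.null(span_pair) || length(units) < 2) return(build(sample(units)))
  rest <- setdiff(units, span_pair)
  side <- if (length(rest)) stats::runif(length(rest)) < 0.5 else logical(0)
  left <- build(sample(c(span_pair[1], rest[side])))
  right <- build(sample(c(span_pair[2], rest[!side])))
  join(left, right)
}

#' Generate a tree with a planted sporulation clade and sigB subclade
#'
#' Builds a rooted tree whose sporulation clade is exactly the MRCA span of
#' the sporulation reference tips and contains a nested sigB subclade
#' (spanned by the sigB reference tips), planted in-clade phage tips, and
#' optionally phage tips inside the sigB subclade. Out-of-clade phage tips
#' and bacterial outgroup tips sit outside.
#'
#' @param n_phage_in_clade Phage tips planted inside the sporulation clade
#'   (outside the sigB subclade).
#' @param n_phage_outside Phage tips planted outside the clade.
#' @param n_phage_in_sigb Phage tips planted inside the sigB subclade.
#' @param spore_refs,sigb_refs Bacterial reference tip labels (>= 2 each so
#'   the references span their clade).
#' @param n_outgroup Bacterial outgroup tips outside the clade.
#' @param seed RNG seed.
#' @return List with `newick`, `metadata` (tip, source, family) and `truth`
#'   (the planted sporulation-like phage tip labels).
#' @export
gen_tree <- function(n_phage_in_clade, n_phage_outside, n_phage_in_sigb = 0L,
                     spore_refs = c("Bs_sigF", "Bs_sigE", "Bs_sigG", "Bs_sigK"),
                     sigb_refs = c("Bs_sigB", "Bc_sigB"),
                     n_outgroup = 2L, seed = 1L) {
  if (length(spore_refs) < 2 || length(sigb_refs) < 2)
    stop("gen_tree: need >= 2 reference tips per set")
  with_seed(seed, {
    p_in <- if (n_phage_in_clade > 0)
      sprintf("phage_in%02d", seq_len(n_phage_in_clade)) else character()
    p_out <- if (n_phage_outside > 0)
      sprintf("phage_out%02d", seq_len(n_phage_outside)) else character()
    p_sigb <- if (n_phage_in_sigb > 0)
      sprintf("phage_sigb%02d", seq_len(n_phage_in_sigb)) else character()
    outg <- sprintf("out_bact%02d", seq_len(n_outgroup))

    sigb_sub <- .random_subtree(c(sigb_refs, p_sigb),
                                span_pair = sigb_refs[1:2])
    # first two spore refs sit on opposite sides of the clade root, so the
    # reference MRCA spans the whole planted clade
    clade <- .random_subtree(c(spore_refs[1:2], spore_refs[-(1:2)], p_in,
                               sigb_sub),
                             span_pair = spore_refs[1:2])
    outside <- .random_subtree(c(outg, p_out), span_pair = NULL)
    newick <- sprintf("(%s:%.4f,%s:%.4f);", clade, stats::runif(1, 0.05, 1),
                      outside, stats::runif(1, 0.05, 1))
    tips <- c(spore_refs, sigb_refs, p_in, p_out, p_sigb, outg)
    metadata <- data.frame(
      tip = tips,
      source = ifelse(grepl("^phage", tips), "phage", "bacterial"),
      family = c(sub(".*_", "", spore_refs), rep("sigB", length(sigb_refs)),
                 rep(NA, length(p_in) + length(p_out) + length(p_sigb)),
                 rep("outgroup", length(outg))),
      stringsAsFactors = FALSE)
    list(newick = newick, metadata = metadata, truth = p_in)
  })
}

#' Generate logistic growth curves with MOI-dependent lysis
#'
#' Uninfected controls follow logistic growth; infected wells multiply the
#' control curve by an exponential decay that begins at an onset time
#' decreasing with log10(MOI), with decay rate `theta` (the lysis strength).
#' Gaussian measurement noise is added and readings floored at zero.
#'
#' @param r Growth rate (per hour). @param K Carrying capacity (OD).
#' @param od0 Inoculum OD. @param mois MOI series, must include 0.
#' @param theta Lysis decay rate (per hour), >= 0.
#' @param onset0 Lysis onset at MOI = 1 (hours).
#' @param onset_slope Onset advance per decade of MOI (hours).
#' @param noise_sd Measurement noise SD (OD units).
#' @param n_replicates Replicate dilution series.
#' @param t_max,dt Time grid (hours), default 16 h sampled every 0.25 h.
#' @param strain Label carried in the output.
#' @param seed RNG seed.
#' @return List with `curves` (long data frame: well, strain, moi, replicate,
#'   time_h, od600) and `truth` (theta plus the noise-free curves).
#' @export
gen_growth_curves <- function(r = 0.8, K = 1.0, od0 = 0.05,
                              mois = c(0, 10^seq(-5, 0)), theta = 1,
                              onset0 = 3, onset_slope = 0.5,
                              noise_sd = 0.005, n_replicates = 3L,
                              t_max = 16, dt = 0.25, strain = "WT",
                              seed = 1L) {
  if (r <= 0 || K <= 0) stop("gen_growth_curves: r and K must be > 0")
  if (theta < 0 || noise_sd < 0) stop("gen_growth_curves: theta, noise_sd >= 0")
  if (!any(mois == 0)) stop("gen_growth_curves: mois must include 0")
  tt <- seq(0, t_max, by = dt)
  control <- K * od0 * exp(r * tt) / (K + od0 * (exp(r * tt) - 1))
  with_seed(seed, {
    rows <- list(); clean <- list(); w <- 0L
    for (rep_id in seq_len(n_replicates)) for (moi in mois) {
      w <- w + 1L
      mu <- control
      if (moi > 0) {
        t_on <- max(0.25, onset0 - onset_slope * log10(moi))
        decay <- ifelse(tt > t_on, exp(-theta * (tt - t_on)), 1)
        mu <- control * decay
      }
      od <- pmax(0, mu + stats::rnorm(length(tt), 0, noise_sd))
      well <- sprintf("W%03d", w)
      rows[[w]] <- data.frame(well = well, strain = strain, moi = moi,
                              replicate = rep_id, time_h = tt, od600 = od,
                              stringsAsFactors = FALSE)
      clean[[w]] <- data.frame(well = well, moi = moi, replicate = rep_id,
                               time_h = tt, od600 = mu,
                               stringsAsFactors = FALSE)
    }
    list(curves = do.call(rbind, rows),
         truth = list(theta = theta,
                      noise_free = do.call(rbind, clean)))
  })
}

#' Generate a flow-cytometry event table with planted populations
#'
#' Cell events are drawn from two bivariate Gaussians on the transformed
#' (FSC-A, FL-A) scale — spores low-fluorescence, vegetative cells high —
#' and mapped back to raw intensities with `sinh`. Singlet FSC-H lies on a
#' proportional line of FSC-A (on the raw scale); doublets carry doubled
#' FSC-A at singlet FSC-H; noise events occupy a low-scatter mode.
#'
#' @param n_events Total events.
#' @param spore_fraction Planted spore fraction among cell events, in (0,1).
#' @param doublet_fraction,noise_fraction Fractions of total events.
#' @param spore_mean,veg_mean Component means, `c(fsc_a, fl_a)` on the
#'   transformed scale.
#' @param comp_sd Per-channel component SD (transformed scale).
#' @param comp_cor Within-component channel correlation.
#' @param noise_mean,noise_sd Transformed FSC-A location/SD of the noise mode.
#' @param beta Raw-scale FSC-H / FSC-A proportionality of singlets.
#' @param h_noise_sd Log-scale jitter of FSC-H around the singlet line.
#' @param cofactor asinh cofactor the transformed scale refers to.
#' @param sample_id,strain,run,treatment Metadata carried on every event.
#' @param seed RNG seed.
#' @return List with `events` (raw-intensity data frame) and `truth`
#'   (per-event planted class: spore / vegetative / doublet / noise).
#' @export
gen_flow_events <- function(n_events, spore_fraction,
                            doublet_fraction = 0.05, noise_fraction = 0.05,
                            spore_mean = c(3.6, 2.5), veg_mean = c(4.0, 7.5),
                            comp_sd = c(0.35, 0.35), comp_cor = 0.2,
                            noise_mean = 1.0, noise_sd = 0.25,
                            beta = 0.9, h_noise_sd = 0.05, cofactor = 1,
                            sample_id = "S1", strain = "wt", run = "run1",
                            treatment = "control", seed = 1L) {
  if (spore_fraction <= 0 || spore_fraction >= 1)
    stop("gen_flow_events: spore_fraction must be in (0,1)")
  if (doublet_fraction + noise_fraction >= 1)
    stop("gen_flow_events: fractions leave no room for cell events")
  Sigma <- diag(comp_sd) %*% matrix(c(1, comp_cor, comp_cor, 1), 2) %*% diag(comp_sd)
  L <- chol(Sigma)
  draw <- function(n, mu)
    sweep(matrix(stats::rnorm(2 * n), nrow = n, ncol = 2) %*% L, 2, -mu)
  with_seed(seed, {
    n_noise <- round(noise_fraction * n_events)
    n_doub <- round(doublet_fraction * n_events)
    n_cells <- n_events - n_noise - n_doub
    is_spore <- stats::runif(n_cells) < spore_fraction
    d_spore <- stats::runif(n_doub) < spore_fraction
    cells <- rbind(draw(sum(is_spore), spore_mean),
                   draw(sum(!is_spore), veg_mean))
    doub <- rbind(draw(sum(d_spore), spore_mean),
                  draw(sum(!d_spore), veg_mean))
    cls <- c(rep("spore", sum(is_spore)), rep("vegetative", sum(!is_spore)),
             rep("doublet", n_doub), rep("noise", n_noise))
    a_t <- c(cells[, 1], doub[, 1], stats::rnorm(n_noise, noise_mean, noise_sd))
    fl_t <- c(cells[, 2], doub[, 2], stats::rnorm(n_noise, noise_mean, 0.3))
    raw_a <- sinh(a_t) * cofactor
    singlet_a <- raw_a
    is_doub <- cls == "doublet"
    raw_a[is_doub] <- 2 * raw_a[is_doub]
    raw_h <- beta * singlet_a * exp(stats::rnorm(length(raw_a), 0, h_noise_sd))
    raw_fl <- pmax(0, sinh(fl_t) * cofactor)
    perm <- sample(length(cls))
    events <- data.frame(event_id = seq_along(perm),
                         sample_id = sample_id, strain = strain, run = run,
                         treatment = treatment,
                         fsc_h = pmax(raw_h[perm], 1e-6),
                         fsc_a = pmax(raw_a[perm], 1e-6),
                         fl_a = raw_fl[perm],
                         stringsAsFactors = FALSE)
    list(events = events,
         truth = data.frame(event_id = seq_along(perm), class = cls[perm],
                            stringsAsFactors = FALSE))
  })
}

#' Generate a differential-expression table with planted enrichment
#'
#' Each gene is independently up-regulated with its class probability
#' (`sporulation_up_prob` for annotated genes, `background_up_prob`
#' otherwise), down-regulated with `down_prob`, else null. Up genes draw
#' log2 fold change > 1 and adjusted p < 0.05; null genes draw log2 fold
#' change near 0 and uniform p.
#'
#' @param n_genes,n_sporulation Universe size and annotated-gene count.
#' @param background_up_prob,sporulation_up_prob Per-class up probabilities.
#' @param down_prob Down probability (both classes).
#' @param effect_size_log2fc Upper scale of drawn fold changes.
#' @param resample_from Optional `truth` of a previous call: reuse its class
#'   draws and jitter its fold changes, emulating a replicate strain with a
#'   near-identical transcriptional profile.
#' @param seed RNG seed.
#' @return List with `table` (gene_id, log2fc, p_adj, is_sporulation) and
#'   `truth` (per-gene class and noise-free log2fc).
#' @export
gen_de_table <- function(n_genes = 4000L,
                         n_sporulation = max(1L, round(n_genes / 8)),
                         background_up_prob = 0.05, sporulation_up_prob = 0.6,
                         down_prob = 0.03, effect_size_log2fc = 3,
                         resample_from = NULL, seed = 1L) {
  if (n_sporulation > n_genes) stop("gen_de_table: K > N")
  with_seed(seed, {
    gene <- sprintf("gene%05d", seq_len(n_genes))
    is_sp <- seq_len(n_genes) <= n_sporulation
    if (is.null(resample_from)) {
      p_up <- ifelse(is_sp, sporulation_up_prob, background_up_prob)
      u <- stats::runif(n_genes)
      class <- ifelse(u < p_up, "up",
                      ifelse(u < p_up + down_prob, "down", "null"))
      base_lfc <- numeric(n_genes)
      base_lfc[class == "up"] <- stats::runif(sum(class == "up"), 1.05,
                                              effect_size_log2fc + 1)
      base_lfc[class == "down"] <- -stats::runif(sum(class == "down"), 1.05,
                                                 effect_size_log2fc + 1)
      base_lfc[class == "null"] <- stats::rnorm(sum(class == "null"), 0, 0.3)
    } else {
      class <- resample_from$class
      base_lfc <- resample_from$base_log2fc
    }
    lfc <- base_lfc + if (is.null(resample_from)) 0 else
      stats::rnorm(n_genes, 0, 0.1)
    p_adj <- numeric(n_genes)
    sig <- class != "null"
    p_adj[sig] <- stats::runif(sum(sig), 1e-6, 0.049)
    p_adj[!sig] <- stats::runif(sum(!sig))
    list(table = data.frame(gene_id = gene, log2fc = lfc, p_adj = p_adj,
                            is_sporulation = is_sp, stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene, class = class,
                            base_log2fc = base_lfc, is_sporulation = is_sp,
                            stringsAsFactors = FALSE))
  })
}
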