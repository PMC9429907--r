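# Phage virulence index from microplate OD curves.
#
# For each multiplicity of infection (MOI), local virulence compares the
# integrated OD of infected wells against uninfected controls over a fixed
# window after infection. The virulence index Vp then integrates local
# virulence across the log10 MOI dilution series and normalizes by the
# theoretical maximum (complete suppression at every MOI), giving a scalar
# in [0, 1].

#' Integrated OD over a time window
#'
#' Trapezoidal area under the OD curve on \[0, t_end\] hours. If `t_end` falls
#' between sampled time points the boundary value is linearly interpolated.
#'
#' @param time_h Increasing numeric vector of times (hours).
#' @param od Non-negative OD readings, same length.
#' @param t_end Window end (hours); must not exceed the last time point.
#' @return Area in OD x hours.
#' @export
integrate_od <- function(time_h, od, t_end) {
  if (length(time_h) != length(od)) stop("integrate_od: length mismatch")
  if (is.unsorted(time_h, strictly = TRUE))
    stop("integrate_od: time points must be strictly increasing")
  if (t_end > max(time_h) + 1e-9) stop("integrate_od: t_end beyond data")
  keep <- time_h <= t_end + 1e-12
  if (sum(keep) < 2) stop("integrate_od: fewer than 2 points before t_end")
  tt <- time_h[keep]; oo <- od[keep]
  if (max(tt) < t_end - 1e-12) {
    oo <- c(oo, stats::approx(time_h, od, xout = t_end)$y)
    tt <- c(tt, t_end)
  }
  pracma::trapz(tt, oo)
}

#' Local virulence at one MOI
#'
#' `1 - area_infected / area_control`, clamped to \[0, 1\]: the fractional
#' suppression of host growth at that phage dose.
#'
#' @param area_infected,area_control Integrated OD areas; control must be > 0.
#' @return Value in \[0, 1\].
#' @export
local_virulence <- function(area_infected, area_control) {
  if (any(area_control <= 0)) stop("local_virulence: control area must be > 0")
  pmin(1, pmax(0, 1 - area_infected / area_control))
}

#' Phage virulence index Vp
#'
#' Computes local virulence at each nonzero MOI (replicates averaged on the
#' local-virulence scale), then the trapezoidal area under local virulence
#' versus log10(MOI), normalized by the same area under the constant 1 —
#' i.e. by complete suppression across the dilution series.
#'
#' @param curves Data frame in long format with columns `moi`, `replicate`,
#'   `time_h`, `od600`, and optionally `well`/`strain`. Must include MOI = 0
#'   control wells and at least two distinct MOI > 0.
#' @param t_end Integration window end in hours (default 6, the time at which
#'   uninfected cultures transition to stationary phase in the assay this
#'   index was designed around).
#' @return A `virulence_result`: list with `vp`, `local` (per-MOI mean local
#'   virulence), `per_replicate` (per-replicate Vp where the replicate has
#'   its own control), `t_end`.
#' @export
virulence_index <- function(curves, t_end = 6) {
  req <- c("moi", "replicate", "time_h", "od600")
  if (!all(req %in% names(curves)))
    stop("virulence_index: curves need columns ", paste(req, collapse = ", "))
  mois <- sort(unique(curves$moi[curves$moi > 0]))
  if (!any(curves$moi == 0)) stop("virulence_index: no MOI = 0 control wells")
  if (length(mois) < 2)
    stop("virulence_index: need >= 2 distinct MOI > 0 to integrate over")

  area_of <- function(sub) integrate_od(sub$time_h, sub$od600, t_end)
  well_key <- interaction(curves$moi, curves$replicate, drop = TRUE)
  wells <- do.call(rbind, lapply(split(curves, well_key), function(sub) {
    data.frame(moi = sub$moi[1], replicate = sub$replicate[1],
               area = area_of(sub[order(sub$time_h), , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  ctrl <- wells[wells$moi == 0, , drop = FALSE]
  ctrl_mean <- mean(ctrl$area)

  # replicate-matched control if present, else mean control area
  ctrl_area_for <- function(rep_id) {
    hit <- ctrl$area[ctrl$replicate == rep_id]
    if (length(hit)) mean(hit) else ctrl_mean
  }
  inf <- wells[wells$moi > 0, , drop = FALSE]
  inf$v <- mapply(function(a, r) local_virulence(a, ctrl_area_for(r)),
                  inf$area, inf$replicate)

  lmoi <- log10(mois)
  span <- max(lmoi) - min(lmoi)
  vp_from <- function(vtab) {
    vbar <- vapply(mois, function(m) mean(vtab$v[vtab$moi == m]), 0)
    pracma::trapz(lmoi, vbar) / span
  }
  vp <- vp_from(inf)
  local <- data.frame(moi = mois,
                      v = vapply(mois, function(m) mean(inf$v[inf$moi == m]), 0))
  per_rep <- vapply(split(inf, inf$replicate), function(sub) {
    if (length(unique(sub$moi)) < 2) return(NA_real_)
    lm <- log10(sort(unique(sub$moi)))
    vbar <- vapply(sort(unique(sub$moi)),
                   function(m) mean(sub$v[sub$moi == m]), 0)
    pracma::trapz(lm, vbar) / (max(lm) - min(lm))
  }, 0)
  out <- list(vp = vp, local = local,
              per_replicate = data.frame(replicate = names(per_rep),
                                         vp = unname(per_rep),
                                         stringsAsFactors = FALSE),
              t_end = t_end)
  class(out) <- "virulence_result"
  out
}

#' @export
print.virulence_result <- function(x, ...) {
  cat(sprintf("Phage virulence index Vp = %.4f (integrated to %g h)\n",
              x$vp, x$t_end))
  cat("Local virulence by MOI:\n")
  print(x$local, row.names = FALSE)
  invisible(x)
}

#' Compare virulence between two strains
#'
#' Welch two-sample t test on per-replicate Vp values of two strains.
#'
#' @param result_a,result_b `virulence_result` objects.
#' @return A `welch_test`.
#' @export
compare_virulence <- function(result_a, result_b) {
  va <- result_a$per_replicate$vp; vb <- result_b$per_replicate$vp
  welch_t_test(va[!is.na(va)], vb[!is.na(vb)])
}
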