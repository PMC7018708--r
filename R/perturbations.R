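#' Reference plating densities (cells/ml)
#'
#' High, low and very-low plating densities used for the density conditions;
#' the high value is the reference density to which the medium coupling is
#' normalised.
#' @export
DENSITY_LEVELS <- c(high = 3.3e5, low = 4.1e4, very_low = 5.2e3)

#' Describe an experimental perturbation condition
#'
#' Encodes one stimulation condition: the stimulus at t = 0 (LPS or PMA, not
#' both), IL-10 pretreatment at -12 h, sTNFR pretreatment at -1 h, brefeldin A
#' (BFA, secretion block) added at 1 or 2 h post-stimulus, the cell-density
#' condition, and the mechanism multipliers. Times are hours post-stimulation
#' (hps); pretreatments occur at negative times.
#'
#' @param lps LPS dose (ng/ml) at t = 0.
#' @param pma PMA dose (ng/ml) at t = 0.
#' @param il10 IL-10 dose (ng/ml) applied at `il10_time`.
#' @param il10_time h, default -12.
#' @param stnfr soluble TNF receptor dose (a.u.; 1 = the 8.3 ug/ml convention)
#'   applied at `stnfr_time`.
#' @param stnfr_time h, default -1.
#' @param bfa_at start time of BFA (h post-stimulus, > 0) or `NA` for none.
#' @param density `"high"`, `"low"`, `"very_low"`, or a positive number taken
#'   as cells/ml.
#' @param m named or length-6 vector of mechanism multipliers (default all 1).
#' @param fbd_threshold LPS dose (ng/ml) at and above which the FBD switch is
#'   engaged; default 1.
#' @return Object of class `perturbation_spec`.
#' @export
#' @examples
#' perturbation(lps = 100, stnfr = 1, density = "high")
perturbation <- function(lps = 0, pma = 0, il10 = 0, il10_time = -12,
                         stnfr = 0, stnfr_time = -1, bfa_at = NA,
                         density = "high", m = NULL, fbd_threshold = 1) {
  if (lps > 0 && pma > 0) stop("LPS and PMA co-stimulation is not an assayed condition")
  if (any(c(lps, pma, il10, stnfr) < 0)) stop("doses must be >= 0")
  if (!is.na(bfa_at) && bfa_at <= 0) stop("bfa_at must be a positive time (hps)")
  if (is.character(density)) {
    density <- match.arg(density, names(DENSITY_LEVELS))
    dens_val <- unname(DENSITY_LEVELS[density])
    dens_lab <- density
  } else {
    if (!is.numeric(density) || density <= 0) stop("density must be > 0")
    dens_val <- density
    dens_lab <- "custom"
  }
  mm <- setNames(rep(1, 6), paste0("m", 1:6))
  if (!is.null(m)) {
    if (is.null(names(m))) names(m) <- paste0("m", seq_along(m))
    mm[names(m)] <- m
  }
  if (any(mm <= 0)) stop("mechanism multipliers must be > 0")
  structure(list(
    lps = lps, pma = pma, il10 = il10, il10_time = il10_time,
    stnfr = stnfr, stnfr_time = stnfr_time, bfa_at = bfa_at,
    density = dens_val, density_label = dens_lab,
    m = mm, fbd_threshold = fbd_threshold
  ), class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("<perturbation>",
      if (x$lps > 0) sprintf("LPS %g ng/ml", x$lps),
      if (x$pma > 0) sprintf("PMA %g ng/ml", x$pma),
      if (x$lps == 0 && x$pma == 0) "no stimulus",
      if (x$il10 > 0) sprintf("+ IL-10 %g ng/ml @ %g h", x$il10, x$il10_time),
      if (x$stnfr > 0) sprintf("+ sTNFR %g @ %g h", x$stnfr, x$stnfr_time),
      if (!is.na(x$bfa_at)) sprintf("+ BFA @ %g hps", x$bfa_at),
      sprintf("| density %s (%.3g cells/ml)", x$density_label, x$density),
      if (fbd_active(x)) "| FBD on" else "| FBD off", "\n")
  invisible(x)
}

#' Is the feedback-dominance switch engaged?
#'
#' The FBD switch (NF-kB-driven transcription of its own RelA subunit) is
#' engaged for TLR4 stimulation at LPS doses at or above the threshold, and
#' never for PMA (which activates IKK through PKC, bypassing TLR4) or for
#' unstimulated cells.
#'
#' @param spec a [perturbation()] object.
#' @return Logical flag.
#' @export
fbd_active <- function(spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  spec$lps >= spec$fbd_threshold && spec$lps > 0
}

#' Build time-dependent model inputs from a perturbation
#'
#' Converts a [perturbation()] into the pure input functions consumed by the
#' ODE right-hand side: saturating (Michaelis-type) receptor drives for LPS,
#' PMA and IL-10, each a step at its treatment time, a BFA indicator, the
#' initial free sTNFR level set at the pretreatment time, the density
#' multiplier (relative to the high-density reference) and the FBD flag.
#' Schedules are pure functions of the spec: the same spec always yields
#' identical input functions.
#'
#' @param spec a [perturbation()] object.
#' @param params parameter vector (supplies the dose half-max constants).
#' @return List with elements `u_lps(t)`, `u_pma(t)`, `u_il10(t)`, `bfa(t)`
#'   (each vectorised over `t`), `stnfr0`, `t_start` (earliest treatment time,
#'   <= 0), `density_mult`, `fbd` and `event_times`.
#' @export
build_schedule <- function(spec, params = default_params()) {
  stopifnot(inherits(spec, "perturbation_spec"))
  sat <- function(dose, K) if (dose <= 0) 0 else dose / (K + dose)
  u_lps_max <- sat(spec$lps, params[["K_lps"]])
  u_pma_max <- sat(spec$pma, params[["K_lps"]])  # shared dose scale
  u_il10_max <- sat(spec$il10, params[["K_il10"]])
  il10_t <- spec$il10_time
  bfa_at <- spec$bfa_at
  list(
    u_lps  = function(t) ifelse(t >= 0, u_lps_max, 0),
    u_pma  = function(t) ifelse(t >= 0, u_pma_max, 0),
    u_il10 = function(t) ifelse(t >= il10_t, u_il10_max, 0),
    bfa    = if (is.na(bfa_at)) function(t) rep(0, length(t))
             else function(t) as.numeric(t >= bfa_at),
    stnfr0 = spec$stnfr,
    t_start = min(0, if (spec$il10 > 0) spec$il10_time else 0,
                  if (spec$stnfr > 0) spec$stnfr_time else 0),
    density_mult = spec$density / unname(DENSITY_LEVELS["high"]),
    fbd = fbd_active(spec),
    event_times = sort(unique(c(0,
      if (spec$il10 > 0) spec$il10_time,
      if (spec$stnfr > 0) spec$stnfr_time,
      if (!is.na(bfa_at)) bfa_at)))
  )
}
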