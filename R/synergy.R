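#' Fit the median-effect equation to a dose-response series
#'
#' The median-effect model `fa/fu = (D/Dm)^m` linearizes to
#' `log10(fa/(1-fa)) = m*log10(D) - m*log10(Dm)`; an ordinary
#' least-squares line on the logit-log scale yields the slope `m` and
#' `Dm = 10^(-intercept/m)`, the median-effect dose (IC50). Fraction
#' affected values are clipped into `[0.005, 0.995]` before the transform
#' so plates with 0%/100% viability remain finite.
#'
#' @param doses strictly positive dose vector (one consistent unit).
#' @param fa fraction affected at each dose (`1 - viability`), in (0, 1).
#' @return a [MedianEffectFit-class]; `ic50(fit)` returns `Dm`.
#' @examples
#' d <- c(0.5, 1, 2, 4, 8)
#' fit <- fitMedianEffect(d, d / (d + 2))  # Dm = 2, m = 1
#' ic50(fit)
#' @export
fitMedianEffect <- function(doses, fa) {
  if (length(doses) != length(fa)) stop("doses and fa lengths differ")
  if (length(doses) < 3L) stop("need at least 3 dose points")
  if (any(!is.finite(doses)) || any(doses <= 0)) stop("doses must be positive")
  fa <- .clip01(fa)
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- fit$coefficients[[2L]]
  if (!is.finite(m) || m <= 0)
    stop("median-effect fit failed: non-positive slope (is the response ",
         "increasing with dose?)")
  dm <- 10^(-fit$coefficients[[1L]] / m)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  new("MedianEffectFit", dm = dm, m = m, r = r, n = length(doses))
}

#' Dose producing a given effect level under a median-effect fit
#'
#' Inverts the median-effect equation: `D = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a [MedianEffectFit-class].
#' @param fa effect level in (0, 1); 0.5 returns the IC50.
#' @return dose in the unit the fit was made in.
#' @export
doseForEffect <- function(fit, fa = 0.5) {
  .check_scalar(fa, "fa")
  if (fa <= 0 || fa >= 1) stop("effect level must be inside (0, 1)")
  fit@dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Molar-ratio scheme for a k-drug combination
#'
#' Returns the tested concentration-ratio grid: `k + 1` settings labeled
#' with roman numerals, the first all ones (equimolar) and each subsequent
#' setting doubling exactly one drug's part in turn. For two drugs this is
#' 1:1, 2:1, 1:2; for five drugs the sixth setting is 1:1:1:1:2.
#'
#' @param k number of drugs, 2 to 5 (the tested range; other sizes error).
#' @return named list of integer part vectors, names `"I"`, `"II"`, ...
#' @examples
#' ratioScheme(2)
#' @export
ratioScheme <- function(k) {
  .check_scalar(k, "k", integer = TRUE)
  if (k < 2 || k > 5)
    stop("ratio schemes are defined for 2 to 5 drugs")
  settings <- c(list(rep(1L, k)),
                lapply(seq_len(k), function(i) { v <- rep(1L, k); v[i] <- 2L; v }))
  names(settings) <- .roman(seq_len(k + 1L))
  settings
}

#' Synergy category of a combination index
#'
#' `ci < 0.3` strong synergy; `0.3 <= ci < 0.9` synergy;
#' `0.9 <= ci <= 1.1` additive; `ci > 1.1` antagonism.
#'
#' @param ci combination index value(s).
#' @return character vector of categories.
#' @export
ciCategory <- function(ci) {
  if (any(!is.finite(ci)) || any(ci < 0)) stop("CI must be non-negative")
  ifelse(ci < 0.3, "strong-synergy",
  ifelse(ci < 0.9, "synergy",
  ifelse(ci <= 1.1, "additive", "antagonism")))
}

#' Chou-Talalay combination index of a fixed-ratio combination
#'
#' The combination is fitted as a single pseudo-agent over total dose. At
#' the requested effect level the total combination dose `Dc` is read off
#' that fit and decomposed into per-drug doses `d_i = Dc * share_i` by the
#' molar-ratio parts. The mutually-exclusive combination index is
#' `CI = sum_i d_i / Dx_i`, where `Dx_i = Dm_i * (fa/(1-fa))^(1/m_i)` is
#' the dose of drug i alone producing the same effect. A sham combination
#' (a drug with itself) yields CI = 1 exactly.
#'
#' @param singleFits named list of [MedianEffectFit-class], one per member
#'   drug, in ratio order.
#' @param comboDoses,comboFa the combination's dose-response series (total
#'   dose; same unit as the single-agent fits).
#' @param ratio integer/numeric parts vector, e.g. `c(2, 1, 1)` for 2:1:1.
#' @param effectLevel fa at which CI is evaluated (default 0.5, the IC50
#'   level).
#' @return list with `ci`, `category`, `effectLevel`, `comboFit`,
#'   `comboDose` and per-drug `doses`/`dx`.
#' @export
combinationIndex <- function(singleFits, comboDoses, comboFa, ratio,
                             effectLevel = 0.5) {
  if (length(singleFits) != length(ratio))
    stop("one single-agent fit per ratio part is required")
  if (any(ratio <= 0)) stop("ratio parts must be positive")
  if (effectLevel <= 0 || effectLevel >= 1)
    stop("effect level must be inside (0, 1)")
  comboFit <- fitMedianEffect(comboDoses, comboFa)
  dc <- doseForEffect(comboFit, effectLevel)
  share <- ratio / sum(ratio)
  di <- dc * share
  dx <- vapply(singleFits, doseForEffect, numeric(1), fa = effectLevel)
  ci <- sum(di / dx)
  list(ci = ci, category = ciCategory(ci), effectLevel = effectLevel,
       comboFit = comboFit, comboDose = dc, doses = di, dx = dx)
}

#' Best experimental IC50 across ratio settings
#'
#' The lowest IC50 across all tested drug ratios is the combination's best
#' experimental result; ties return the first label.
#'
#' @param ic50s positive numeric vector of per-ratio IC50 values.
#' @param labels ratio labels (defaults to roman numerals).
#' @return list with `value` and `label`.
#' @examples
#' bestIC50(c(90.43, 31.37, 30.88, 42.94))  # 30.88 at III
#' @export
bestIC50 <- function(ic50s, labels = .roman(seq_along(ic50s))) {
  if (!length(ic50s)) stop("empty IC50 list")
  if (any(!is.finite(ic50s)) || any(ic50s <= 0))
    stop("IC50 values must be positive")
  i <- which.min(ic50s)
  list(value = ic50s[i], label = labels[i])
}

#' Relative potency of a reference IC50 against a comparator
#'
#' @param referenceIC50,comparatorIC50 positive scalars in the same unit.
#' @return list with `percent` (100 * reference / comparator, one
#'   decimal) and `fold` (comparator / reference).
#' @examples
#' relativePotency(115.5, 207.6)  # 55.6 percent, 1.80-fold
#' @export
relativePotency <- function(referenceIC50, comparatorIC50) {
  .check_scalar(referenceIC50, "referenceIC50", lower = 1e-300)
  .check_scalar(comparatorIC50, "comparatorIC50", lower = 1e-300)
  list(percent = round(100 * referenceIC50 / comparatorIC50, 1),
       fold = comparatorIC50 / referenceIC50)
}

#' Analyze a dose-response plate table
#'
#' Takes the long-format plate table (see [readPlateTable()]): control
#' wells (dose 0) define the untreated viability; fraction affected is
#' `1 - viability/control`; replicate wells are averaged per dose before
#' fitting. Every (combination, ratio) series is fitted by
#' [fitMedianEffect()]; for multi-drug combinations with all member
#' monotherapy series present, the combination index at `effectLevel` is
#' added.
#'
#' @param plate data.frame with columns `combination_id`, `ratio_label`,
#'   `drug_id`, `dose`, `unit`, `viability_fraction`, `replicate`. `dose`
#'   is the total well concentration, repeated across member-drug rows of
#'   a combination well.
#' @param effectLevel fa at which CI is evaluated (default 0.5).
#' @return data.frame with one row per (combination, ratio): `ic50`,
#'   `dm`, `m`, `r`, `ci`, `category`.
#' @export
analyzePlates <- function(plate, effectLevel = 0.5) {
  req <- c("combination_id", "ratio_label", "drug_id", "dose", "unit",
           "viability_fraction", "replicate")
  if (!all(req %in% names(plate)))
    stop("plate table must have columns ", paste(req, collapse = ", "))
  if (length(unique(plate$unit)) > 1L)
    stop("mixed dose units in one analysis: ",
         paste(unique(plate$unit), collapse = ", "),
         " (convert explicitly first)")

  series <- .plate_series(plate)
  singles <- series[vapply(series, function(s) length(s$members) == 1L, TRUE)]
  names(singles) <- vapply(singles, function(s) s$members, "")

  rows <- lapply(series, function(s) {
    fit <- fitMedianEffect(s$doses, s$fa)
    ci <- NA_real_; cat <- NA_character_
    if (length(s$members) > 1L && all(s$members %in% names(singles))) {
      sf <- lapply(singles[s$members], function(x)
        fitMedianEffect(x$doses, x$fa))
      res <- combinationIndex(sf, s$doses, s$fa, s$ratio, effectLevel)
      ci <- res$ci; cat <- res$category
    }
    data.frame(combination_id = s$id, ratio_label = s$label,
               ic50 = ic50(fit), dm = fit@dm, m = fit@m, r = fit@r,
               ci = ci, category = cat)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$combination_id, out$ratio_label), , drop = FALSE]
}

## Collapse a plate table into per-(combination, ratio) fa series.
.plate_series <- function(plate) {
  key <- paste(plate$combination_id, plate$ratio_label, sep = "\r")
  lapply(split(plate, key), function(g) {
    members <- unique(g$drug_id)  # first-appearance order
    members <- members[nzchar(members)]
    ctrl <- g$dose == 0
    control <- if (any(ctrl)) mean(g$viability_fraction[ctrl]) else 1
    g <- g[!ctrl, , drop = FALSE]
    ## average replicate wells per total dose before fitting
    fa_by_dose <- tapply(1 - g$viability_fraction / control, g$dose, mean)
    doses <- as.numeric(names(fa_by_dose))
    ratio <- if (length(members) > 1L) {
      sch <- ratioScheme(length(members))
      lbl <- unique(g$ratio_label)
      if (!lbl %in% names(sch))
        stop("unknown ratio label ", lbl, " for ", length(members), " drugs")
      sch[[lbl]]
    } else 1L
    list(id = unique(g$combination_id), label = unique(g$ratio_label),
         members = members, ratio = ratio,
         doses = doses, fa = as.numeric(fa_by_dose))
  })
}
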