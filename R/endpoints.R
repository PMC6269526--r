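# Wound closure, noncompartmental PK and the group/time statistics helper.

#' Open-wound area as percent of the original area
#'
#' `100 * area(mask_t) / area(mask_0)`. Values above 100% are reported
#' as-is (early wounds can expand before they contract).
#'
#' @param mask_t,mask_0 binary wound masks of the same shape (TRUE = open).
#' @param pixel_size_mm optional pixel size; areas are pixel counts, so it
#'   cancels, but it is validated for consistency when given.
#' @return percent of original area.
#' @export
closure_fraction <- function(mask_t, mask_0, pixel_size_mm = NULL) {
  mask_t <- mask_t > 0; mask_0 <- mask_0 > 0
  if (!identical(dim(mask_t), dim(mask_0)))
    stop("masks must share one shape", call. = FALSE)
  a0 <- sum(mask_0)
  if (a0 == 0) stop("day-0 mask is empty", call. = FALSE)
  100 * sum(mask_t) / a0
}

#' Wound area in mm^2
#' @param mask binary mask (TRUE = open wound).
#' @param pixel_size_mm pixel size in mm/px.
#' @return area in mm^2.
#' @export
wound_area <- function(mask, pixel_size_mm) {
  stopifnot_scalar(pixel_size_mm, "pixel_size_mm", positive = TRUE)
  sum(mask > 0) * pixel_size_mm^2
}

#' Closure time course from a mask series
#'
#' @param masks named list of binary masks (names = days); the first entry
#'   is day 0.
#' @param pixel_size_mm pixel size in mm/px.
#' @return data.frame `day`, `area_mm2`, `pct_original`.
#' @export
closure_series <- function(masks, pixel_size_mm) {
  days <- as.numeric(names(masks))
  data.frame(
    day = days,
    area_mm2 = vapply(masks, wound_area, numeric(1),
                      pixel_size_mm = pixel_size_mm),
    pct_original = vapply(masks, closure_fraction, numeric(1),
                          mask_0 = masks[[1]]),
    row.names = NULL
  )
}

#' Maximum concentration and its time
#'
#' Maximum observed concentration (Cmax) and the earliest time at which it
#' occurs (Tmax); ties go to the earliest sample.
#'
#' @param profile a `PKProfile` or data.frame with `time_h`, `conc`.
#' @return list(cmax, tmax_h).
#' @export
cmax_tmax <- function(profile) {
  if (nrow(profile) < 1) stop("profile is empty", call. = FALSE)
  i <- which.max(profile$conc)   # which.max returns the first maximum
  list(cmax = profile$conc[i], tmax_h = profile$time_h[i])
}

#' Trapezoidal area under the concentration-time curve
#'
#' Linear trapezoidal rule over the observed sampling window only — no
#' extrapolation to infinity, matching exposure reported "over the sampled
#' period".
#'
#' @param profile a `PKProfile` or data.frame with `time_h`, `conc`
#'   (strictly increasing times, >= 2 samples).
#' @return AUC in conc * h units.
#' @export
auc_trapezoid <- function(profile) {
  if (nrow(profile) < 2) stop("need >= 2 samples for AUC", call. = FALSE)
  t <- profile$time_h; c <- profile$conc
  if (any(diff(t) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(c < 0)) stop("concentrations must be >= 0", call. = FALSE)
  pracma::trapz(t, c)
}

#' Noncompartmental PK summary
#'
#' @param profile a `PKProfile`.
#' @return data.frame with `cmax`, `tmax_h`, `auc` over the sampled window.
#' @export
pk_summary <- function(profile) {
  ct <- cmax_tmax(profile)
  data.frame(cmax = ct$cmax, tmax_h = ct$tmax_h, auc = auc_trapezoid(profile))
}

#' Two-way ANOVA with Tukey-adjusted group comparisons per timepoint
#'
#' Fits `value ~ group * time` (both factors) by ordinary two-factor
#' analysis of variance and reports Tukey-adjusted pairwise group contrasts
#' within each timepoint (via \pkg{emmeans}), with significance tiers
#' matching the conventional star notation: * p < 0.05, ** p < 0.01,
#' *** p < 0.001, **** p < 0.0001.
#'
#' @param data data.frame with columns `value`, `group`, `time` (and
#'   anything else, ignored). Needs >= 2 groups, >= 2 timepoints and >= 2
#'   replicates in every group x time cell.
#' @param alpha_tiers tier cut points, largest first.
#' @return list of class `GroupComparison`: `anova` (the two-way ANOVA
#'   table), `contrasts` (data.frame contrast, time, estimate, SE, df,
#'   t.ratio, p.value, tier), `alpha_tiers`.
#' @export
group_compare <- function(data, alpha_tiers = c(0.05, 0.01, 0.001, 1e-4)) {
  need <- c("value", "group", "time")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- data.frame(value = as.numeric(data$value),
                  group = factor(data$group), time = factor(data$time))
  if (nlevels(d$group) < 2 || nlevels(d$time) < 2)
    stop("need >= 2 groups and >= 2 timepoints", call. = FALSE)
  cell_n <- table(d$group, d$time)
  if (any(cell_n == 0)) stop("empty group x time cells", call. = FALSE)
  if (any(cell_n < 2))
    stop("need >= 2 replicates in every group x time cell", call. = FALSE)
  fit <- stats::aov(value ~ group * time, data = d)
  emm <- emmeans::emmeans(fit, ~ group | time)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  contrasts <- data.frame(
    contrast = as.character(prs$contrast),
    time = as.character(prs$time),
    estimate = prs$estimate, SE = prs$SE, df = prs$df,
    t.ratio = prs$t.ratio, p.value = prs$p.value,
    tier = significance_tier(prs$p.value, alpha_tiers),
    stringsAsFactors = FALSE
  )
  structure(list(anova = summary(fit), contrasts = contrasts,
                 alpha_tiers = alpha_tiers),
            class = "GroupComparison")
}

#' Star notation for p-values
#'
#' @param p numeric p-values.
#' @param alpha_tiers tier cut points, largest first (default
#'   0.05/0.01/0.001/0.0001).
#' @return character vector: "ns", "*", "**", "***", "****".
#' @export
significance_tier <- function(p, alpha_tiers = c(0.05, 0.01, 0.001, 1e-4)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    k <- sum(pi < alpha_tiers)
    if (k == 0) "ns" else strrep("*", k)
  }, character(1))
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Two-way ANOVA (group x time), Tukey-adjusted group contrasts\n\n")
  print(x$anova)
  cat("\nPairwise group contrasts per timepoint:\n")
  df <- x$contrasts
  df$p.value <- signif(df$p.value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
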