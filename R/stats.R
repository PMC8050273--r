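#' Assemble a long-format band proportion table
#'
#' One row per (subject, stream, band) cell; missing cells are permitted
#' (the mixed models tolerate them).
#'
#' @param subject,stream,band,value parallel vectors; `stream` is typically
#'   `"ventral"`/`"lateral"`, `band` a band label or index.
#' @param roi,hemisphere optional annotations.
#' @return data.frame with factor columns ready for the ANOVA wrappers.
#' @export
longTable <- function(subject, stream, band, value, roi = NULL,
                      hemisphere = NULL) {
  out <- data.frame(subject = factor(subject), stream = factor(stream),
                    band = factor(band), value = as.numeric(value))
  if (!is.null(roi)) out$roi <- factor(roi)
  if (!is.null(hemisphere)) out$hemisphere <- factor(hemisphere)
  out
}

# partial eta squared from an F statistic
#' Partial eta squared from an F statistic
#'
#' `F df1 / (F df1 + df2)`, the F-based equivalent of
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared.
#' @examples
#' partialEtaSq(10, 3, 30)  # 0.5
#' @export
partialEtaSq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Repeated-measures LMM ANOVA for band x stream designs
#'
#' Fits `value ~ band * stream + (1 | subject)` by REML and evaluates the
#' fixed effects with Type III F tests using Satterthwaite degrees of
#' freedom; partial eta squared is reported per effect. Singular fits are
#' flagged, not hidden.
#'
#' @param table long-format data.frame from [longTable()] (>= 2 subjects,
#'   >= 2 bands, both streams).
#' @return list with `anova` (data.frame: effect, F, df1, df2, p, petaSq),
#'   `model` (the `lmerModLmerTest` fit) and `singular` flag.
#' @export
bandByStreamAnova <- function(table) {
  stopifnot(all(c("subject", "stream", "band", "value") %in% names(table)))
  if (nlevels(droplevels(factor(table$subject))) < 2L)
    stop("need at least 2 subjects")
  if (nlevels(droplevels(factor(table$band))) < 2L)
    stop("need at least 2 bands")
  if (nlevels(droplevels(factor(table$stream))) < 2L)
    stop("both streams must be present")
  m <- lmerTest::lmer(value ~ band * stream + (1 | subject), data = table)
  .lmmAnova(m)
}

#' Three-way LMM ANOVA with hemisphere
#'
#' The hemisphere-lateralization variant:
#' `value ~ band * roi * hemisphere + (1 | subject)` with Type III
#' Satterthwaite F tests.
#'
#' @param table long table with `roi` and `hemisphere` columns.
#' @return same structure as [bandByStreamAnova()].
#' @export
bandROIHemisphereAnova <- function(table) {
  stopifnot(all(c("subject", "band", "roi", "hemisphere", "value") %in%
                  names(table)))
  for (f in c("band", "roi", "hemisphere"))
    if (nlevels(droplevels(factor(table[[f]]))) < 2L)
      stop("factor '", f, "' needs at least 2 levels")
  m <- lmerTest::lmer(value ~ band * roi * hemisphere + (1 | subject),
                      data = table)
  .lmmAnova(m)
}

.lmmAnova <- function(m) {
  a <- stats::anova(m, type = 3)     # lmerTest: Satterthwaite by default
  out <- data.frame(
    effect = rownames(a),
    F = a[["F value"]],
    df1 = a[["NumDF"]],
    df2 = a[["DenDF"]],
    p = a[["Pr(>F)"]])
  out$petaSq <- partialEtaSq(out$F, out$df1, out$df2)
  rownames(out) <- NULL
  list(anova = out, model = m, singular = lme4::isSingular(m))
}

#' Tukey HSD post-hoc contrasts for a fitted LMM
#'
#' All pairwise contrasts of one factor (optionally within levels of
#' another), Tukey-adjusted at family-wise confidence 0.95. Degrees of
#' freedom follow the requested method (Satterthwaite by default, matching
#' the omnibus tests; `"asymptotic"` gives the classical z-based variant for
#' comparison).
#'
#' @param fit result of [bandByStreamAnova()] (or a `lmerMod` directly).
#' @param factorName factor whose levels are compared.
#' @param by optional conditioning factor.
#' @param dfMethod `"satterthwaite"`, `"kenward-roger"` or `"asymptotic"`.
#' @return data.frame of contrasts with Tukey-adjusted p values.
#' @export
tukeyPosthoc <- function(fit, factorName, by = NULL,
                         dfMethod = "satterthwaite") {
  m <- if (is.list(fit) && !is.null(fit$model)) fit$model else fit
  spec <- stats::as.formula(paste(
    "~", factorName, if (!is.null(by)) paste("|", by) else ""))
  em <- emmeans::emmeans(m, spec, lmer.df = dfMethod)
  as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey")))
}

#' Paired comparison of per-subject stream summaries
#'
#' Paired t test on per-subject (ventral, lateral) value pairs; incomplete
#' pairs are dropped. Cohen's d for paired data is
#' `mean(diff) / sd(diff)`. Zero-variance differences are degenerate and
#' flagged rather than tested.
#'
#' @param ventral,lateral per-subject summary values (equal length; NA marks
#'   a missing cell).
#' @return list with `t`, `df`, `p`, `d`, `meanDiff`, `nPairs` and
#'   `degenerate` flag.
#' @export
pairedStreamTest <- function(ventral, lateral) {
  stopifnot(length(ventral) == length(lateral))
  ok <- stats::complete.cases(ventral, lateral)
  v <- ventral[ok]; l <- lateral[ok]
  if (length(v) < 3L) stop("need at least 3 complete pairs")
  d <- v - l
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, d = 0,
                  meanDiff = 0, nPairs = length(d), degenerate = FALSE))
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                d = NA_real_, meanDiff = mean(d), nPairs = length(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(v, l, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / stats::sd(d), meanDiff = mean(d),
       nPairs = length(d), degenerate = FALSE)
}

#' Cohen's d for two groups or paired differences
#'
#' Paired: `mean(x - y) / sd(x - y)`. Unpaired: mean difference over the
#' pooled SD.
#'
#' @param x,y numeric samples.
#' @param paired treat as paired?
#' @return Cohen's d.
#' @export
cohensD <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    if (all(d == 0)) return(0)
    return(mean(d) / stats::sd(d))
  }
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}
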