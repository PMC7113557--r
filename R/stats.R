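#' Long-format normalized ratios
#'
#' Reshapes session records into one row per subject x condition x post-probe
#' session, with the normalized MEP ratio as response. Flagged sessions
#' (quality exclusions) are dropped.
#'
#' @param records a `session_records` data frame.
#' @param session_labels labels for the post probes (minutes after PAS).
#' @return a data frame with columns `subject`, `condition`, `session`,
#'   `ratio` (factors for the first three).
#' @export
records_long <- function(records, session_labels = c("2min", "17min", "32min")) {
  stopifnot(is.data.frame(records))
  records <- records[!records$flagged, , drop = FALSE]
  long <- do.call(rbind, lapply(1:3, function(k)
    data.frame(subject = records$subject, condition = records$condition,
               session = session_labels[k],
               ratio = records[[paste0("ratio", k)]],
               stringsAsFactors = FALSE)))
  long$subject <- factor(long$subject)
  long$condition <- factor(long$condition)
  long$session <- factor(long$session, levels = session_labels)
  long
}

#' Mixed-design repeated-measures ANOVA on normalized MEP ratios
#'
#' Fits the study's statistical model to the normalized data: fixed effects of
#' ISI timing CONDITION, post-PAS probe SESSION (2, 17, 32 min after PAS) and
#' their interaction, with a random intercept per rat accounting for the
#' randomized block design. Estimation is by REML and type-III F tests are
#' reported with Satterthwaite denominator degrees of freedom (hence possibly
#' fractional).
#'
#' @param records a `session_records` data frame (>= 2 subjects, >= 2
#'   conditions, 3 post sessions per record).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return an object of class `pas_anova`: a data frame with one row per term
#'   (interaction, condition, session) and columns `term`, `df_num`, `df_den`,
#'   `F`, `p`. Degenerate inputs (e.g. constant response) yield `NA` entries
#'   rather than an error.
#' @export
fit_mixed_anova <- function(records, alpha = 0.05) {
  long <- records_long(records)
  long <- long[is.finite(long$ratio), , drop = FALSE]
  empty <- setdiff(levels(long$condition), unique(as.character(long$condition)))
  if (length(empty)) {
    warning("dropping condition(s) with no data: ",
            paste(empty, collapse = ", "))
    long$condition <- droplevels(long$condition)
  }
  if (nlevels(factor(long$subject)) < 2 || nlevels(long$condition) < 2)
    stop("need at least 2 subjects and 2 conditions")
  terms <- c("condition:session", "condition", "session")
  out <- data.frame(term = c("session x condition", "condition", "session"),
                    df_num = NA_real_, df_den = NA_real_,
                    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(ratio ~ condition * session + (1 | subject), data = long,
                     REML = TRUE,
                     contrasts = list(condition = "contr.sum",
                                      session = "contr.sum")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    an <- tryCatch(
      suppressMessages(suppressWarnings(
        stats::anova(fit, type = "III", ddf = "Satterthwaite"))),
      error = function(e) NULL)
    if (!is.null(an)) {
      for (i in seq_along(terms)) {
        j <- match(terms[i], rownames(an))
        if (!is.na(j)) {
          out$df_num[i] <- an$NumDF[j]
          out$df_den[i] <- an$DenDF[j]
          out$F[i] <- an$`F value`[j]
          out$p[i] <- an$`Pr(>F)`[j]
        }
      }
    }
  }
  structure(out, class = c("pas_anova", "data.frame"),
            estimation = "REML", ddf = "Satterthwaite", alpha = alpha)
}

#' @export
print.pas_anova <- function(x, ...) {
  cat(sprintf("Mixed-effects ANOVA on normalized MEP ratios (type III, %s, %s ddf)\n",
              attr(x, "estimation"), attr(x, "ddf")))
  df <- as.data.frame(x)
  df$df_num <- round(df$df_num, 2)
  df$df_den <- round(df$df_den, 2)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Winsorize a numeric vector
#'
#' Replaces values beyond the `p` and `1 - p` quantiles by those quantiles.
#'
#' @param x numeric vector.
#' @param p per-tail winsorization level (default 0.05).
#' @return the winsorized vector.
#' @export
winsorize <- function(x, p = 0.05) {
  stopifnot(p >= 0, p < 0.5)
  q <- stats::quantile(x, c(p, 1 - p), na.rm = TRUE, names = FALSE)
  pmin(pmax(x, q[1]), q[2])
}

#' Carryover (cumulative PAS effect) analysis
#'
#' Tests whether the change induced by a PAS session predicts the change in
#' baseline excitability the next day. For every pair of consecutive test days
#' of a subject with unchanged stimulation parameters, computes the
#' Within-Session MEP Ratio (mean post / mean pre on day N) and the Next-Day
#' Baseline MEP Ratio (mean pre on day N+1 / mean pre on day N), and returns
#' their Pearson correlation with its p value, plus the same after
#' winsorization of both variables.
#'
#' @param records a `session_records` data frame ordered or orderable by
#'   `day` within subject; pairs are used only when `day` values are
#'   consecutive integers, neither session is flagged, and the cortical and
#'   muscle stimulation intensities are identical across the two days.
#' @param winsor_p per-tail winsorization level (default 0.05).
#' @return an object of class `pas_carryover`: list with `r`, `p`,
#'   `r_winsorized`, `p_winsorized`, `n_pairs` and the pair table `data`.
#' @export
carryover_analysis <- function(records, winsor_p = 0.05) {
  stopifnot(is.data.frame(records))
  records <- records[!records$flagged, , drop = FALSE]
  pairs <- list()
  for (s in unique(records$subject)) {
    rs <- records[records$subject == s, , drop = FALSE]
    rs <- rs[order(rs$day), , drop = FALSE]
    if (nrow(rs) < 2L) next
    for (i in seq_len(nrow(rs) - 1L)) {
      a <- rs[i, ]
      b <- rs[i + 1L, ]
      if (b$day != a$day + 1L) next
      if (a$cortex_uA != b$cortex_uA || a$muscle_mA != b$muscle_mA) next
      pre_a <- mean(c(a$pre1, a$pre2, a$pre3))
      post_a <- mean(c(a$post1, a$post2, a$post3))
      pre_b <- mean(c(b$pre1, b$pre2, b$pre3))
      pairs[[length(pairs) + 1L]] <- data.frame(
        subject = s, day = a$day,
        within_session_ratio = post_a / pre_a,
        next_day_baseline_ratio = pre_b / pre_a)
    }
  }
  if (length(pairs) < 3L)
    stop("insufficient data: fewer than 3 valid consecutive-day pairs")
  d <- do.call(rbind, pairs)
  ct <- stats::cor.test(d$within_session_ratio, d$next_day_baseline_ratio,
                        method = "pearson")
  ctw <- stats::cor.test(winsorize(d$within_session_ratio, winsor_p),
                         winsorize(d$next_day_baseline_ratio, winsor_p),
                         method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 r_winsorized = unname(ctw$estimate),
                 p_winsorized = ctw$p.value,
                 n_pairs = nrow(d), data = d),
            class = "pas_carryover")
}

#' @export
print.pas_carryover <- function(x, ...) {
  cat(sprintf("Carryover analysis over %d consecutive-day pairs:\n", x$n_pairs))
  cat(sprintf("  r = %.3f (p = %.3g); winsorized r = %.3f (p = %.3g)\n",
              x$r, x$p, x$r_winsorized, x$p_winsorized))
  invisible(x)
}
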