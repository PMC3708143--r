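#' Peak phase of a burst
#'
#' Midpoint of onset and offset; computed per trial when testing condition
#' effects on peak timing.
#'
#' @param onset,offset phases, `offset > onset`.
#' @return `(onset + offset) / 2`.
#' @export
peak_phase <- function(onset, offset) {
  (onset + offset) / 2
}

#' One-way fixed-effects ANOVA across conditions
#'
#' Classic between/within F test via [stats::oneway.test()] with equal
#' variances assumed. Degenerate inputs are resolved to their limits: all
#' values identical gives `F = 0, p = 1`; zero within-group variance with
#' unequal means gives `F = Inf, p = 0`.
#'
#' @param groups list of >= 2 numeric vectors (each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
synergy_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- nlevels(g) - 1L
  df2 <- length(x) - nlevels(g)
  within_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (within_ss == 0) {
    if (max(means) - min(means) == 0) {
      return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    }
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1L]),
       df2 = unname(ft$parameter[2L]), p = unname(ft$p.value))
}

#' Pairwise Welch t-test between two conditions
#'
#' Two-sample t with the Welch-Satterthwaite degrees of freedom via
#' [stats::t.test()]. Two constant groups with equal means return
#' `t = 0, p = 1`; constant groups with different means return `p = 0`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
pairwise_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = unname(tt$p.value))
}

#' Burst magnitude as a percentage of the control condition
#'
#' `100 * mean(condition magnitudes) / mean(control magnitudes)`; the control
#' condition is 100% by definition. Undefined for bursts inactive in the
#' control condition (no control trials or zero control mean) — such bursts
#' cannot be expressed relative to control.
#'
#' @param condition_mag per-trial magnitudes in the condition of interest.
#' @param control_mag per-trial magnitudes in the control (unobstructed)
#'   condition.
#' @return percentage, or `NA` with attribute `reason` when undefined.
#' @export
magnitude_percent <- function(condition_mag, control_mag) {
  condition_mag <- condition_mag[!is.na(condition_mag)]
  control_mag <- control_mag[!is.na(control_mag)]
  if (!length(control_mag)) {
    out <- NA_real_
    attr(out, "reason") <- "absent in control"
    return(out)
  }
  cm <- mean(control_mag)
  if (cm <= 0) stop("undefined control: control mean magnitude must be positive")
  100 * mean(condition_mag) / cm
}

#' Scale a direct component by its members' magnitude change
#'
#' The DC amplitude is multiplied by the mean of the member bursts' magnitude
#' percentages (relative to control) over members with defined control
#' activity; bursts inactive in control are excluded. If no member has a
#' defined percentage the scale falls back to 1 with a warning.
#'
#' @param dc a [direct_component()].
#' @param member_percent numeric vector of member percentages (may contain NA).
#' @return a `direct_component` whose `amplitude` is the scale
#'   (peak value = scale), with element `scale` recorded.
#' @export
scale_dc <- function(dc, member_percent) {
  ok <- member_percent[!is.na(member_percent)]
  if (!length(ok)) {
    warning("no member burst has defined control activity; scale set to 1")
    s <- 1
  } else {
    s <- mean(ok) / 100
  }
  out <- dc
  out$amplitude <- dc$amplitude * s
  out$scale <- s
  out
}

#' Map constrained clusters onto unconstrained clusters
#'
#' For each constrained cluster, lists every unconstrained cluster sharing at
#' least one member burst, with the Euclidean centroid distance of each pair
#' (0 when memberships and data are identical). A constrained cluster split
#' across several unconstrained clusters yields one row per fragment.
#'
#' @param constrained,unconstrained `cluster_solution`s over the same bursts.
#' @return data.frame with columns `constrained_id`, `constrained_members`,
#'   `unconstrained_id`, `shared_members`, `distance`.
#' @export
compare_solutions <- function(constrained, unconstrained) {
  rows <- list()
  for (cc in constrained$clusters) {
    for (uc in unconstrained$clusters) {
      shared <- intersect(cc$members, uc$members)
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        constrained_id = cc$id,
        constrained_members = paste(cc$members, collapse = "+"),
        unconstrained_id = uc$id,
        shared_members = paste(shared, collapse = "+"),
        distance = centroid_distance(cc, uc),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phase and magnitude statistics of synergies across conditions
#'
#' For each synergy of the constrained reference composition, pools the
#' per-trial onset, offset, peak phase and (when present) duration-normalized
#' magnitude of every member burst, runs a one-way ANOVA across conditions for
#' each measure, and Welch pairwise t-tests between condition pairs for
#' measures with a significant (`p < alpha`) condition effect. Per-muscle
#' magnitude percentages relative to the control condition are also reported.
#'
#' @param bt full [burst_table()] covering all conditions.
#' @param reference a `cluster_solution` defining synergy composition.
#' @param conditions conditions to compare (first = control).
#' @param alpha significance level gating the pairwise tests (default 0.05).
#' @param bonferroni apply Bonferroni correction across the pairwise tests of
#'   each synergy/measure? Default FALSE, reporting raw pairwise p values.
#' @return list with data.frames `anova` (synergy x measure),
#'   `pairwise`, and `magnitude` (per burst label x condition percentages).
#' @export
compare_conditions <- function(bt, reference, conditions = VALID_CONDITIONS,
                               alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(reference, "cluster_solution"))
  control <- conditions[1L]
  measures <- c("onset", "offset", "peak", "magnitude")
  pairs <- utils::combn(conditions, 2L, simplify = FALSE)
  anova_rows <- list(); pw_rows <- list(); mag_rows <- list()

  pull <- function(cond, members, measure) {
    tr <- bt[bt$condition == cond & bt$burst_label %in% members, ]
    switch(measure,
      onset = tr$onset,
      offset = tr$offset,
      peak = peak_phase(tr$onset, tr$offset),
      magnitude = tr$magnitude[!is.na(tr$magnitude)]
    )
  }

  for (cl in reference$clusters) {
    for (ms in measures) {
      grp <- lapply(conditions, pull, members = cl$members, measure = ms)
      names(grp) <- conditions
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp) < 2L) next
      an <- synergy_anova(grp)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        synergy_id = cl$id, measure = ms, F = an$F, df1 = an$df1,
        df2 = an$df2, p = an$p, stringsAsFactors = FALSE
      )
      if (is.finite(an$p) && an$p < alpha) {
        kpairs <- Filter(function(pr) all(pr %in% names(grp)), pairs)
        for (pr in kpairs) {
          tt <- pairwise_t(grp[[pr[1L]]], grp[[pr[2L]]])
          p <- tt$p
          if (bonferroni) p <- min(1, p * length(kpairs))
          pw_rows[[length(pw_rows) + 1L]] <- data.frame(
            synergy_id = cl$id, measure = ms,
            condition_a = pr[1L], condition_b = pr[2L],
            t = tt$t, df = tt$df, p = p, stringsAsFactors = FALSE
          )
        }
      }
    }
    for (lb in cl$members) {
      ctrl <- bt$magnitude[bt$condition == control & bt$burst_label == lb]
      ctrl <- ctrl[!is.na(ctrl)]
      for (cond in setdiff(conditions, control)) {
        cm <- bt$magnitude[bt$condition == cond & bt$burst_label == lb]
        cm <- cm[!is.na(cm)]
        pct <- if (!length(cm)) NA_real_ else if (!length(ctrl)) {
          NA_real_
        } else magnitude_percent(cm, ctrl)
        mag_rows[[length(mag_rows) + 1L]] <- data.frame(
          synergy_id = cl$id, burst_label = lb, condition = cond,
          percent = as.numeric(pct),
          defined = length(cm) > 0 && length(ctrl) > 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    anova = do.call(rbind, anova_rows),
    pairwise = if (length(pw_rows)) do.call(rbind, pw_rows) else NULL,
    magnitude = do.call(rbind, mag_rows)
  )
}
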