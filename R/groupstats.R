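#' Per-section summary statistics by group
#'
#' For a stated section level, each individual is summarized by the
#' arithmetic mean of its 360 radial values there; groups are then
#' summarized by the mean, standard deviation and range of those individual
#' means.  The canonical reporting levels are 35%, 50% and 65% of length;
#' other levels are allowed but flagged.
#'
#' @param values_by_individual list of per-individual 17 x 360 matrices
#'   (raw thickness or SMA profiles, or standardized maps).
#' @param groups group label per individual.
#' @param fraction section level in percent of length.
#' @param fractions the row levels of the matrices (default
#'   `seq(25, 65, by = 2.5)`).
#' @return a `section_summary` data.frame: one row per group with `n`,
#'   `mean`, `sd`, `min`, `max`, plus attributes `individual_means` and
#'   `fraction`.
#' @export
section_summary <- function(values_by_individual, groups, fraction,
                            fractions = seq(25, 65, by = 2.5)) {
  stopifnot(length(values_by_individual) == length(groups))
  if (!fraction %in% c(35, 50, 65))
    warning(sprintf("fraction %.1f%% is not a canonical reporting level (35/50/65)",
                    fraction))
  row <- match(fraction, fractions)
  if (is.na(row)) stop("requested fraction is not among the section levels")
  ind <- vapply(values_by_individual, function(m) mean(m[row, ]), numeric(1))
  groups <- factor(groups)
  out <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(ind, groups, mean)),
    sd = as.numeric(tapply(ind, groups, function(v)
      if (length(v) > 1) stats::sd(v) else NA_real_)),
    min = as.numeric(tapply(ind, groups, min)),
    max = as.numeric(tapply(ind, groups, max)))
  structure(out, individual_means = ind, groups = groups,
            fraction = fraction, class = c("section_summary", "data.frame"))
}

#' One-way ANOVA with Student-Newman-Keuls post hoc comparisons
#'
#' Fits a one-way ANOVA on per-individual means and, when warranted, runs
#' the Student-Newman-Keuls (SNK) stepwise range procedure on the ordered
#' group means: the observed studentized range of each pair is compared to
#' the critical value for the number of means spanned; non-significant
#' ranges block all sub-ranges they contain.  Significant pairs are
#' reported in "X > Y" form.
#'
#' @param values numeric vector of per-individual values.
#' @param groups group label per value (>= 2 groups, each n >= 2).
#' @param alpha significance level for the post hoc tests (default 0.05).
#' @return list with `F`, `p`, `df` (c(between, within)), `snk` (data.frame
#'   of all pairs: groups, spanned means, q statistic, critical value,
#'   significance) and `significant` (character vector of "X > Y" strings).
#' @export
anova_snk <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs n >= 2")
  n <- length(values)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- k - 1
  dfw <- n - k
  msw <- ssw / dfw
  if (ssw + ssb < .Machine$double.eps * n) {
    return(list(F = NA_real_, p = 1, df = c(between = dfb, within = dfw),
                snk = NULL, significant = character(0)))
  }
  Fstat <- (ssb / dfb) / msw
  p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)

  ord <- order(gm)
  means <- gm[ord]
  nn <- as.numeric(ns[ord])
  pairs <- list()
  blocked <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      se <- sqrt(msw / 2 * (1 / nn[i] + 1 / nn[j]))
      q <- (means[j] - means[i]) / se
      qcrit <- stats::qtukey(1 - alpha, span, dfw)
      sig <- !blocked[i, j] && q > qcrit
      if (!sig && !blocked[i, j]) {
        # block all sub-ranges of a non-significant range
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
        blocked[i, j] <- TRUE
      }
      pairs[[length(pairs) + 1]] <- data.frame(
        higher = names(means)[j], lower = names(means)[i],
        span = span, q = q, q_crit = qcrit, significant = sig)
    }
  }
  snk <- do.call(rbind, pairs)
  sig <- snk[snk$significant, , drop = FALSE]
  list(F = unname(Fstat), p = unname(p),
       df = c(between = dfb, within = dfw), snk = snk,
       significant = sprintf("%s > %s", sig$higher, sig$lower))
}

#' Export a group summary table (mean / sd / range / comparisons) as CSV
#'
#' Mirrors the layout of per-section comparative tables: one row per group
#' and section level with mean, sd, range, and the significant SNK pairs.
#'
#' @param summaries named list of [section_summary()] outputs (names =
#'   section level labels).
#' @param path output CSV path.
#' @param alpha significance level passed to [anova_snk()].
#' @return the assembled data.frame, invisibly.
#' @export
export_group_table <- function(summaries, path, alpha = 0.05) {
  rows <- list()
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    a <- anova_snk(attr(s, "individual_means"), attr(s, "groups"),
                   alpha = alpha)
    rows[[nm]] <- data.frame(
      level = nm, group = s$group, n = s$n, mean = s$mean, sd = s$sd,
      range = sprintf("%.3g-%.3g", s$min, s$max),
      anova_p = a$p,
      significant = paste(a$significant, collapse = "; "))
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
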