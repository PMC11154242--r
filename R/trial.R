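#' Validate and construct a trial ledger
#'
#' One row per animal: which of the ten experimental groups it belonged
#' to, the resection method, the tumor-bed treatment, whether it died
#' perioperatively (within hours of the procedure, before any recurrence
#' information could accrue) and whether tumor recurrence was observed
#' within the 90-day follow-up.
#'
#' @param df Data frame with columns `animal_id`, `group_id` (1-10),
#'   `resection` (`cold_knife`/`laser_scalpel`), `treatment` (`pdt_405`,
#'   `pdt_660`, `irr_405`, `irr_660`, `none`), `perioperative_death`
#'   (logical), `recurrence` (logical; must be `NA` for perioperative
#'   deaths), `time_to_event_days` (<= 90, `NA` when censored or dead).
#' @return The validated data frame with class `trial_ledger`.
#' @export
trial_ledger <- function(df) {
  required <- c("animal_id", "group_id", "resection", "treatment",
                "perioperative_death", "recurrence", "time_to_event_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    .pdt_validation_error(paste("ledger is missing columns:",
                                paste(missing_cols, collapse = ", ")))
  if (!all(df$resection %in% c("cold_knife", "laser_scalpel")))
    .pdt_validation_error("`resection` must be cold_knife or laser_scalpel")
  if (!all(df$treatment %in% c("pdt_405", "pdt_660", "irr_405", "irr_660", "none")))
    .pdt_validation_error("unknown `treatment` level")
  df$perioperative_death <- as.logical(df$perioperative_death)
  df$recurrence <- as.logical(df$recurrence)
  if (any(df$perioperative_death & !is.na(df$recurrence)))
    .pdt_validation_error(
      "recurrence must be NA for perioperative deaths (no follow-up exists)")
  # each group maps to exactly one (resection, treatment) pair
  combos <- unique(df[, c("group_id", "resection", "treatment")])
  if (anyDuplicated(combos$group_id))
    .pdt_validation_error("a group_id maps to more than one (resection, treatment)")
  tte <- df$time_to_event_days
  if (any(!is.na(tte) & (tte < 0 | tte > 90)))
    .pdt_validation_error("`time_to_event_days` must be within [0, 90]")
  class(df) <- c("trial_ledger", "data.frame")
  df
}

# round half away from zero (round-half-up for the non-negative rates used
# here); base R's round() goes to even
round_half_up <- function(x) floor(x + 0.5)

#' Per-group recurrence summaries
#'
#' Perioperative deaths are excluded from the denominator: those animals
#' died within about two hours of the procedure and contribute no
#' recurrence information. Rates are reported both at full precision and
#' rounded half-up to integer percent; 95% Clopper-Pearson intervals are
#' attached.
#'
#' @param ledger A [trial_ledger()] (or a data frame accepted by it).
#' @param conf_level Confidence level for the exact binomial interval.
#' @return A data frame of class `group_summary` with one row per group:
#'   `group_id`, `resection`, `treatment`, `n_enrolled`,
#'   `n_perioperative_deaths`, `n_evaluable`, `n_recurrent`,
#'   `rate_percent`, `rate_percent_reported`, `ci95_low`, `ci95_high`
#'   (percent). A group with zero evaluable animals gets `NA` rates and is
#'   flagged in `note`.
#' @export
summarize_groups <- function(ledger, conf_level = 0.95) {
  if (!inherits(ledger, "trial_ledger")) ledger <- trial_ledger(ledger)
  groups <- sort(unique(ledger$group_id))
  rows <- lapply(groups, function(gid) {
    sub <- ledger[ledger$group_id == gid, ]
    n_enrolled <- nrow(sub)
    n_dead <- sum(sub$perioperative_death)
    n_eval <- n_enrolled - n_dead
    n_rec <- sum(sub$recurrence[!sub$perioperative_death], na.rm = TRUE)
    if (n_eval == 0L) {
      return(data.frame(
        group_id = gid, resection = sub$resection[1], treatment = sub$treatment[1],
        n_enrolled = n_enrolled, n_perioperative_deaths = n_dead,
        n_evaluable = 0L, n_recurrent = 0L,
        rate_percent = NA_real_, rate_percent_reported = NA_real_,
        ci95_low = NA_real_, ci95_high = NA_real_,
        note = "no evaluable animals; rate undefined"))
    }
    rate <- 100 * n_rec / n_eval
    ci <- exact_binomial_ci(n_rec, n_eval, level = conf_level)
    data.frame(
      group_id = gid, resection = sub$resection[1], treatment = sub$treatment[1],
      n_enrolled = n_enrolled, n_perioperative_deaths = n_dead,
      n_evaluable = n_eval, n_recurrent = n_rec,
      rate_percent = rate, rate_percent_reported = round_half_up(rate),
      ci95_low = 100 * unname(ci[1]), ci95_high = 100 * unname(ci[2]),
      note = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval from binomial tail inversion, computed through the beta
#' quantile form: `low = qbeta(alpha/2, k, n - k + 1)`,
#' `high = qbeta(1 - alpha/2, k + 1, n - k)`, with the conventional
#' boundary values `low = 0` at `k = 0` and `high = 1` at `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)` on the probability scale.
#' @examples
#' exact_binomial_ci(7, 10)
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    .pdt_validation_error("`n` must be a positive integer")
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n || k != round(k))
    .pdt_validation_error("`k` must be an integer in [0, n]")
  alpha <- 1 - level
  low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, over the hypergeometric distribution with
#' the observed margins, the probabilities of all tables no more probable
#' than the observed one (the standard "probability method"). The odds
#' ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model, with 0 / Inf returned when the
#' observed count sits at the edge of its support.
#'
#' @param a,b,c,d Cell counts, row-wise: `a`,`b` = group A
#'   recurrent/non-recurrent, `c`,`d` = group B recurrent/non-recurrent.
#' @param group_a,group_b Optional labels carried into the result.
#' @return A `pairwise_comparison` list: `group_a`, `group_b`, `table`,
#'   `odds_ratio`, `fisher_p_two_sided`.
#' @examples
#' fisher_exact(11, 1, 0, 11)
#' @export
fisher_exact <- function(a, b, c, d, group_a = "A", group_b = "B") {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    .pdt_validation_error("cells must be non-negative integers")
  if (sum(cells) == 0)
    .pdt_validation_error("all-zero table")
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, k, (m + n2) - k, m)
  p_obs <- dhyper(a, k, (m + n2) - k, m)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)

  odds_ratio <- .conditional_or_mle(a, support, probs)

  structure(
    list(group_a = group_a, group_b = group_b,
         table = matrix(cells, 2, 2, byrow = TRUE,
                        dimnames = list(c(group_a, group_b),
                                        c("recurrent", "non_recurrent"))),
         odds_ratio = odds_ratio, fisher_p_two_sided = p),
    class = "pairwise_comparison")
}

# conditional MLE of the odds ratio: solve E_psi[X] = a under the
# noncentral hypergeometric distribution on the given support
.conditional_or_mle <- function(a, support, central_probs) {
  if (length(support) == 1L) return(NA_real_)  # margin fixes the table
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  mean_x <- function(log_psi) {
    w <- log(central_probs) + support * log_psi
    w <- exp(w - max(w))
    sum(support * w) / sum(w) - a
  }
  root <- uniroot(mean_x, lower = -30, upper = 30, tol = 1e-10)
  exp(root$root)
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("<pairwise_comparison> %s vs %s: OR = %.4g, p = %.4g\n",
              x$group_a, x$group_b, x$odds_ratio, x$fisher_p_two_sided))
  print(x$table)
  invisible(x)
}

#' Recurrence report: table and grouped bar chart
#'
#' @param summaries A `group_summary` from [summarize_groups()].
#' @param comparisons Optional list of `pairwise_comparison` objects.
#' @param out_dir Directory to write into (created if needed).
#' @param chart Write a grouped bar chart (`recurrence_rates.png`)?
#' @return Invisibly, a list with the paths written: `csv`, `markdown` and
#'   (optionally) `chart`.
#' @export
recurrence_report <- function(summaries, comparisons = list(),
                              out_dir = ".", chart = TRUE) {
  stopifnot(inherits(summaries, "group_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(out_dir, "recurrence_summary.csv")
  write.csv(as.data.frame(summaries), csv_path, row.names = FALSE)

  md_path <- file.path(out_dir, "recurrence_summary.md")
  lines <- c(
    "| Group | Resection | Treatment | Enrolled (deaths) | Recurrence | Rate | 95% CI |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %d | %s | %s | %d (%d) | %d/%d | %s%% | [%.1f, %.1f]%% |",
            summaries$group_id, summaries$resection, summaries$treatment,
            summaries$n_enrolled, summaries$n_perioperative_deaths,
            summaries$n_recurrent, summaries$n_evaluable,
            ifelse(is.na(summaries$rate_percent_reported), "NA",
                   format(summaries$rate_percent_reported)),
            summaries$ci95_low, summaries$ci95_high))
  if (length(comparisons)) {
    lines <- c(lines, "", "| Comparison | Odds ratio | Fisher p (2-sided) |",
               "|---|---|---|",
               vapply(comparisons, function(cmp) sprintf(
                 "| %s vs %s | %.3g | %.4g |", cmp$group_a, cmp$group_b,
                 cmp$odds_ratio, cmp$fisher_p_two_sided), character(1)))
  }
  writeLines(lines, md_path)

  out <- list(csv = csv_path, markdown = md_path)
  if (chart) {
    chart_path <- file.path(out_dir, "recurrence_rates.png")
    grDevices::png(chart_path, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    rates <- summaries$rate_percent_reported
    cols <- ifelse(summaries$resection == "laser_scalpel", "steelblue", "firebrick")
    bp <- graphics::barplot(
      rates, names.arg = paste0("G", summaries$group_id),
      col = cols, ylim = c(0, 105), ylab = "Recurrence rate, %",
      main = "Tumor recurrence by resection method and tumor-bed treatment")
    graphics::text(bp, rates + 4, labels = paste0(rates, "%"))
    graphics::legend("topleft", fill = c("steelblue", "firebrick"),
                     legend = c("laser scalpel", "cold knife"), bty = "n")
    out$chart <- chart_path
  }
  invisible(out)
}
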