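#' Two-group comparison by Student's t-test
#'
#' Two-sided pooled-variance (equal-variance) t-test with mean +- sample
#' SD per group and a two-tier significance annotation: `"*"` for
#' P < 0.05, `"**"` for P < 0.01, `"ns"` otherwise, plus letter-style
#' annotations as used in comparison tables (different lower-case letters
#' mark P < 0.05, different capital letters P < 0.01).
#'
#' @param values_a,values_b numeric vectors, n >= 2 each.
#' @param labels group labels (length 2).
#' @param parameter name of the compared quantity.
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(values_a, values_b, labels = c("A", "B"),
                           parameter = "value") {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  tt <- tryCatch(t.test(values_a, values_b, var.equal = TRUE),
                 error = function(e) {
                   # (near-)zero variance, e.g. uniform phantom populations
                   same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
                   list(statistic = if (same) 0 else
                     sign(mean(values_a) - mean(values_b)) * Inf,
                     p.value = if (same) 1 else 0)
                 })
  p <- tt$p.value
  tier <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  lower <- if (p < 0.05) c("a", "b") else c("a", "a")
  upper <- if (p < 0.01) c("A", "B") else c("A", "A")
  structure(list(
    parameter = parameter, labels = labels,
    means = c(mean(values_a), mean(values_b)),
    sds = c(sd(values_a), sd(values_b)),
    n = c(length(values_a), length(values_b)),
    t_statistic = unname(tt$statistic), p_value = p,
    tier = tier, letters_lower = lower, letters_upper = upper),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s %.4g +- %.3g vs %s %.4g +- %.3g; t = %.3f, p = %.4g [%s]\n",
              x$parameter, x$labels[1], x$means[1], x$sds[1],
              x$labels[2], x$means[2], x$sds[2],
              x$t_statistic, x$p_value, x$tier))
  invisible(x)
}

#' Two-group comparison table of morphometric records
#'
#' One row per (region, band, parameter) with mean +- SD per group, the
#' pooled t-test, tier and significance letters. Entries undetectable in
#' half or more cells of either group are reported as `"-"` (undetectable)
#' without a test.
#'
#' @param records a `morphometric_record` data.frame with `group` column
#'   (e.g. rows of [measure_3d()] bound together).
#' @param parameters measurement columns to compare.
#' @param groups two group labels; defaults to the ones present.
#' @return data.frame (class `comparison_report`).
#' @export
build_report <- function(records,
                         parameters = c("volume_um3", "surface_area_um2",
                                        "concentration_fg_um3",
                                        "dry_mass_pg", "sphericity"),
                         groups = NULL) {
  if (is.null(groups)) groups <- unique(records$group)
  if (length(groups) < 2)
    stop("need >= 2 groups; available: ",
         paste(unique(records$group), collapse = ", "))
  groups <- groups[1:2]
  if (!all(groups %in% records$group))
    stop("missing group(s); available: ",
         paste(unique(records$group), collapse = ", "))
  rows <- list()
  for (rg in unique(records$region)) for (bd in unique(records$band)) {
    sub <- records[records$region == rg & records$band == bd, ]
    if (nrow(sub) == 0) next
    for (pp in parameters) {
      va <- sub[[pp]][sub$group == groups[1] & sub$detectable]
      vb <- sub[[pp]][sub$group == groups[2] & sub$detectable]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      na_all <- sum(sub$group == groups[1])
      nb_all <- sum(sub$group == groups[2])
      undet <- length(va) < max(2, na_all / 2) ||
        length(vb) < max(2, nb_all / 2)
      if (undet) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, band = bd, parameter = pp,
          mean_a = NA_real_, sd_a = NA_real_,
          mean_b = NA_real_, sd_b = NA_real_,
          t = NA_real_, p = NA_real_, tier = "-",
          summary_a = "-", summary_b = "-")
      } else {
        cmp <- compare_groups(va, vb, groups, pp)
        lt <- if (cmp$p_value < 0.01) cmp$letters_upper
          else cmp$letters_lower
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, band = bd, parameter = pp,
          mean_a = cmp$means[1], sd_a = cmp$sds[1],
          mean_b = cmp$means[2], sd_b = cmp$sds[2],
          t = cmp$t_statistic, p = cmp$p_value, tier = cmp$tier,
          summary_a = sprintf("%.4g ± %.3g %s", cmp$means[1],
                              cmp$sds[1], lt[1]),
          summary_b = sprintf("%.4g ± %.3g %s", cmp$means[2],
                              cmp$sds[2], lt[2]))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  class(out) <- c("comparison_report", class(out))
  out
}

#' Render a comparison report as Markdown
#' @param report a [build_report()] result.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  g <- attr(report, "groups")
  hdr <- sprintf("| Region | Band | Parameter | %s | %s | p | |",
                 g[1], g[2])
  sep <- "|---|---|---|---|---|---|---|"
  body <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    sprintf("| %s | %s | %s | %s | %s | %s | %s |", r$region, r$band,
            r$parameter, r$summary_a, r$summary_b,
            ifelse(is.na(r$p), "-", sprintf("%.3g", r$p)),
            ifelse(r$tier %in% c("*", "**"), r$tier, ""))
  }, character(1))
  c(hdr, sep, body)
}
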