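#' Percentage decrease in tract count
#'
#' `100 * (n_healthy - n_lesioned) / n_healthy`, the per-case outcome of the
#' hemisphere comparison; negative when the lesioned side carries more
#' tracts than the healthy reference.
#'
#' @param n_healthy tract count in the healthy hemisphere (> 0).
#' @param n_lesioned tract count in the lesioned hemisphere.
#' @export
percent_decrease <- function(n_healthy, n_lesioned) {
  if (any(n_healthy <= 0)) stop("healthy-hemisphere tract count must be positive")
  100 * (n_healthy - n_lesioned) / n_healthy
}

#' Weight a percentage decrease by tumor volume
#'
#' Divides the percentage decrease by the patient's tumor volume (cm^3),
#' giving a damage density in %/cm^3 that accounts for lesion extent.
#'
#' @param pct percentage decrease.
#' @param volume tumor volume in cm^3 (> 0).
#' @export
ponder_by_volume <- function(pct, volume) {
  if (any(volume <= 0)) stop("tumor volume must be positive")
  pct / volume
}

#' Read a cohort table
#'
#' Accepts either the clinical-table headers (`Case no.`, `Age(yrs)`,
#' `Sex`, `Tumor location`, `Tumor size(cm^3)`, `MIB-1%`, `Percentage
#' decrease in tract count`) or their snake_case equivalents, and returns a
#' normalized tibble. The tumor group (`meningioma`, `LGG`, `HGG`) is taken
#' from a `group` column when present, otherwise derived from the case-id
#' prefix (M/LGG/HGG).
#'
#' @param path CSV file path.
#' @return tibble with columns `case_id`, `group`, `age`, `sex`,
#'   `location`, `tumor_volume_cm3`, `mib1_pct`, `pct_decrease`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(trimws(names(df)))
  pick <- function(...) {
    for (cand in c(...)) {
      hit <- which(nm == cand)
      if (length(hit)) return(df[[hit[1]]])
    }
    NULL
  }
  case_id <- pick("case no.", "case_id", "case")
  pct <- pick("percentage decrease in tract count", "pct_decrease")
  if (is.character(pct)) pct <- as.numeric(sub("%", "", pct))
  out <- tibble::tibble(
    case_id = as.character(case_id),
    group = pick("group") %||% dplyr::case_when(
      grepl("^HGG", case_id) ~ "HGG",
      grepl("^LGG", case_id) ~ "LGG",
      grepl("^M", case_id) ~ "meningioma",
      TRUE ~ NA_character_),
    age = as.numeric(pick("age(yrs)", "age")),
    sex = as.character(pick("sex") %||% NA),
    location = as.character(pick("tumor location", "location") %||% NA),
    tumor_volume_cm3 = as.numeric(pick("tumor size(cm^3)", "tumor_volume_cm3",
                                       "tumor_volume")),
    mib1_pct = as.numeric(pick("mib-1%", "mib1_pct", "mib1")),
    pct_decrease = pct)
  stopifnot(all(out$tumor_volume_cm3 > 0), all(out$mib1_pct >= 0),
            all(out$pct_decrease <= 100))
  out
}

#' Path of the packaged 16-case clinical cohort table
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "table1.csv", package = "mirrortract", mustWork = TRUE)
}

#' Regress volume-weighted tract decrease on the MIB-1 index
#'
#' Simple linear regression of the tumor-volume-weighted percentage
#' decrease (`pct_decrease / tumor_volume_cm3`) on the MIB-1 labeling
#' index: Pearson correlation, least-squares slope and intercept, and the
#' two-sided p-value from `t = r * sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees
#' of freedom.
#'
#' @param table cohort tibble (see [read_cohort()]).
#' @return an object of class `mib1_fit` with [generics::tidy()] /
#'   [generics::glance()] methods.
#' @export
regress_mib1 <- function(table) {
  stopifnot(nrow(table) >= 3)
  x <- table$mib1_pct
  y <- ponder_by_volume(table$pct_decrease, table$tumor_volume_cm3)
  if (stats::sd(x) == 0) stop("MIB-1 values are constant; correlation undefined")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
       sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, slope = slope, intercept = intercept, t = tstat,
                 p = p, n = n, data = tibble::tibble(mib1 = x, weighted_pct = y)),
            class = "mib1_fit")
}

#' @export
print.mib1_fit <- function(x, ...) {
  cat("<mib1_fit> r = ", sprintf("%.3f", x$r), ", p = ", format(x$p, digits = 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @method tidy mib1_fit
#' @export
tidy.mib1_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "mib1_pct"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance mib1_fit
#' @export
glance.mib1_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r^2, statistic = x$t,
                 p.value = x$p, df = x$n - 2, nobs = x$n)
}

#' Per-group mean and SD of the percentage decrease
#'
#' @param table cohort tibble.
#' @param groups optional subset of groups; default all.
#' @return tibble with `group`, `n`, `mean_pct`, `sd_pct` (sample SD, n-1).
#' @export
group_summary <- function(table, groups = NULL) {
  if (!is.null(groups)) table <- dplyr::filter(table, .data$group %in% groups)
  out <- dplyr::summarise(dplyr::group_by(table, .data$group),
                          n = dplyr::n(),
                          mean_pct = mean(.data$pct_decrease),
                          sd_pct = stats::sd(.data$pct_decrease),
                          .groups = "drop")
  if (any(out$n < 2)) stop("each summarised group needs at least 2 cases")
  out
}

#' Two-sample test of percentage decrease between tumor groups
#'
#' Pooled-variance two-sample t-test (df = n_a + n_b - 2) by default, with
#' Welch's unequal-variance variant available; two-sided p.
#'
#' @param table cohort tibble.
#' @param groups_a,groups_b character vectors of group labels for each side.
#' @param var_equal use the pooled-variance test (default) or Welch's.
#' @return tibble with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
group_difference_test <- function(table, groups_a, groups_b, var_equal = TRUE) {
  a <- table$pct_decrease[table$group %in% groups_a]
  b <- table$pct_decrease[table$group %in% groups_b]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 cases per side")
  na <- length(a); nb <- length(b)
  if (var_equal) {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    if (sp2 == 0) stop("degenerate (zero) pooled variance")
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    if (va + vb == 0) stop("degenerate (zero) variance")
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  tibble::tibble(t = tstat, df = df, p = p,
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

#' Full cohort report
#'
#' Regression, per-group summaries, and the meningioma-vs-glioma contrast
#' in one list, as printed by the `cohort-stats` command.
#'
#' @param table cohort tibble.
#' @export
cohort_report <- function(table) {
  fit <- regress_mib1(table)
  list(regression = fit,
       groups = group_summary(table),
       meningioma_vs_glioma = group_difference_test(
         table, "meningioma", c("LGG", "HGG")))
}
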