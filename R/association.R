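# Diplotype-phenotype association: within-sex standardisation, OLS
# regression of bioelectrical phenotypes on haplotype copy number with a
# sex covariate, groupwise Student t tests under the study's grouping
# schemes, and Pearson correlation of ordinal phenotypes.

#' Standardise a phenotype within sex
#'
#' Within each sex the value becomes `(x - sex mean) / sex SD`, then the
#' standardised values are pooled, removing the sex main effect so both
#' sexes can be analysed together.
#'
#' @param values Numeric phenotype vector.
#' @param sex Aligned vector of `"M"`/`"F"` labels.
#' @return Standardised numeric vector (NA preserved).
#' @export
sex_zscore <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  out <- rep(NA_real_, length(values))
  for (s in unique(sex[!is.na(sex)])) {
    idx <- which(sex == s & !is.na(values))
    if (length(idx) < 2L)
      stop("need >= 2 non-missing values for sex ", s)
    sd_s <- stats::sd(values[idx])
    if (sd_s == 0) stop("zero within-sex SD for sex ", s)
    out[idx] <- (values[idx] - mean(values[idx])) / sd_s
  }
  out
}

#' Regress a phenotype on diplotype with sex as covariate
#'
#' Ordinary least squares of the phenotype on a genotype code plus a sex
#' indicator. `additive` coding uses copies of the `b` haplotype (0/1/2);
#' `carrier` uses presence/absence (0/1). Rows with missing values are
#' dropped listwise and the used n reported.
#'
#' @param phenotype Numeric response.
#' @param b_copies Copies of the effect haplotype per subject (0/1/2).
#' @param sex `"M"`/`"F"` labels.
#' @param coding `"additive"` or `"carrier"`.
#' @return Data frame of class `regression_fit`: one row per term
#'   (`genotype`, `sexM` — female is the reference level) with `beta`,
#'   `se`, `t_stat`, `p_value`; attribute `n_used`.
#' @export
fit_diplotype_regression <- function(phenotype, b_copies, sex = NULL,
                                     coding = c("additive", "carrier")) {
  coding <- match.arg(coding)
  g <- if (coding == "carrier") as.numeric(b_copies > 0) else
    as.numeric(b_copies)
  df <- data.frame(y = phenotype, genotype = g)
  if (!is.null(sex)) df$sex <- factor(sex, levels = c("F", "M"))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("need >= 3 complete subjects")
  use_sex <- !is.null(sex) && nlevels(droplevels(df$sex)) >= 2
  if (!is.null(sex) && !use_sex && stats::var(df$genotype) == 0)
    stop("rank-deficient design; collinear term(s): genotype, sex")
  fml <- if (use_sex) y ~ genotype + sex else y ~ genotype
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                    t_stat = cf[, 3], p_value = cf[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_used") <- nrow(df)
  attr(out, "fit") <- fit
  class(out) <- c("regression_fit", "data.frame")
  out
}

#' Groupwise Student t tests per bioelectrical variable
#'
#' Classical pooled-variance two-sample t tests of each variable between
#' two diplotype groups (e.g. `aa` vs `b-carrier`), optionally stratified
#' by sex. Strata where either group has fewer than 2 subjects are
#' reported as not applicable (`NA` statistics, `note = "sample too
#' small"`).
#'
#' @param data Data frame holding the variables, a `group` column with
#'   exactly two levels, and a `sex` column when stratifying.
#' @param variables Character vector of variable names to test.
#' @param group Name of the two-level grouping column (default
#'   `"group"`).
#' @param stratify_by_sex Run the tests within each sex as well.
#' @return Data frame: `stratum`, `variable`, `n1`, `n2`, `t_stat`,
#'   `p_value`, `note`.
#' @export
groupwise_tests <- function(data, variables, group = "group",
                            stratify_by_sex = FALSE) {
  data <- as.data.frame(data)
  lv <- unique(stats::na.omit(data[[group]]))
  if (length(lv) != 2L) stop("grouping column must have exactly 2 levels")
  strata <- list(all = rep(TRUE, nrow(data)))
  if (stratify_by_sex) {
    for (s in c("M", "F")) strata[[s]] <- data$sex == s
  }
  out <- list()
  for (st in names(strata)) {
    for (v in variables) {
      x <- data[strata[[st]] & data[[group]] == lv[1], v]
      y <- data[strata[[st]] & data[[group]] == lv[2], v]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, variable = v, n1 = length(x), n2 = length(y),
          t_stat = NA_real_, p_value = NA_real_,
          note = "sample too small", stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(x, y, var.equal = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, variable = v, n1 = length(x), n2 = length(y),
          t_stat = unname(tt$statistic), p_value = tt$p.value,
          note = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation between capsaicin threshold and an ordinal code
#'
#' @param thresholds Ordinal capsaicin threshold categories (1-10).
#' @param codes Aligned ordinal codes (e.g. food-frequency 0/1/2).
#' @return Pearson r over pairwise-complete observations.
#' @export
threshold_correlation <- function(thresholds, codes) {
  stopifnot(length(thresholds) == length(codes))
  ok <- !is.na(thresholds) & !is.na(codes)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(thresholds[ok]) == 0 || stats::sd(codes[ok]) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(thresholds[ok], codes[ok])
}

#' Association table across the four bioelectrical phenotypes
#'
#' Runs [fit_diplotype_regression()] for each of `rsp`, `xcsp`, `zsp`,
#' `pha` (or any supplied set) and tabulates the genotype term, shaped
#' like a per-phenotype beta/t/p report.
#'
#' @param data Data frame with the phenotype columns, `b_copies` and
#'   `sex`.
#' @param phenotypes Phenotype column names.
#' @param coding Genotype coding, see [fit_diplotype_regression()].
#' @param bonferroni Add a Bonferroni-adjusted p column (an extension
#'   beyond the raw-p reporting convention; off by default).
#' @return Data frame: `phenotype`, `beta`, `t_stat`, `p_value`,
#'   `n_used` (+ `p_bonferroni`).
#' @export
association_table <- function(data,
                              phenotypes = c("rsp", "xcsp", "zsp", "pha"),
                              coding = "additive", bonferroni = FALSE) {
  rows <- lapply(phenotypes, function(ph) {
    fit <- fit_diplotype_regression(data[[ph]], data$b_copies, data$sex,
                                    coding)
    g <- fit[fit$term == "genotype", ]
    data.frame(phenotype = ph, beta = g$beta, t_stat = g$t_stat,
               p_value = g$p_value, n_used = attr(fit, "n_used"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p_bonferroni <- stats::p.adjust(out$p_value, "bonferroni")
  out
}
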