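# Cohort statistics: scalar-statistic ROC AUC with stratified bootstrap
# CIs, correlation screening against the MFCC block, AIC-based linear model
# selection, one-way ANOVA and descriptive tables.

#' ROC AUC of a scalar statistic
#'
#' Full threshold-sweep AUC, computed as the normalized Mann-Whitney
#' pair-count statistic (ties contribute 0.5): the probability that a random
#' subject from the positive-direction class scores above a random subject
#' from the other class. With `direction = "controls_higher"` the AUC is
#' P(control > case) + 0.5 P(tie), matching a biomarker that is depressed by
#' disease.
#'
#' @param values numeric scores.
#' @param labels vector with exactly two classes.
#' @param controls label of the class expected to score higher; defaults to
#'   `"control"` when present, otherwise the first level.
#' @return AUC in `[0, 1]`.
#' @export
auc_scalar <- function(values, labels, controls = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2 || any(table(labels) == 0)) {
    phon_stop("invalidLabels", "need exactly two non-empty classes")
  }
  if (is.null(controls)) {
    controls <- if ("control" %in% classes) "control" else classes[1]
  }
  pos <- labels == controls
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(values, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Bootstrap confidence interval for the scalar AUC
#'
#' Stratified resampling within each class; percentile interval at
#' `alpha/2` and `1 - alpha/2`. Deterministic under a fixed seed.
#'
#' @param values,labels,controls as in [auc_scalar()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param alpha two-sided miscoverage (default 0.05 for a 95% CI).
#' @param seed RNG seed.
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_cases`, `n_controls`, `direction`.
#' @export
bootstrap_auc_ci <- function(values, labels, controls = NULL, n_boot = 2000,
                             alpha = 0.05, seed = 1) {
  labels <- as.character(labels)
  point <- auc_scalar(values, labels, controls)
  classes <- unique(labels)
  if (is.null(controls)) {
    controls <- if ("control" %in% classes) "control" else classes[1]
  }
  ic <- which(labels == controls); io <- which(labels != controls)
  if (min(length(ic), length(io)) < 5) {
    phon_warn("fewer than 5 subjects in a class; bootstrap CI unstable")
  }
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i1 <- sample(ic, length(ic), replace = TRUE)
      i2 <- sample(io, length(io), replace = TRUE)
      auc_scalar(values[c(i1, i2)], labels[c(i1, i2)], controls)
    }, numeric(1))
  })
  ci <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(list(auc = point,
                 ci_low = min(ci[1], point), ci_high = max(ci[2], point),
                 n_boot = n_boot,
                 n_cases = length(io), n_controls = length(ic),
                 direction = paste0(controls, "_higher")),
            class = "roc_result")
}

#' Correlation screen of interpretable features against the MFCC block
#'
#' Computes the full correlation matrix between `other_columns` (rows) and
#' `mfcc_columns` (columns) and retains the rows whose maximum absolute
#' correlation with any MFCC column exceeds `threshold`. Constant columns
#' get correlation 0 with a warning.
#'
#' @param table data.frame of per-subject features.
#' @param mfcc_columns,other_columns character vectors of column names.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param threshold retention threshold on `max |r|` (default 0.3).
#' @param min_rows minimum rows required (default 10).
#' @return object of class `correlation_screen`: `matrix` (retained rows x
#'   mfcc columns), `full_matrix`, `retained`, `method`, `threshold`.
#' @export
correlation_screen <- function(table, mfcc_columns, other_columns,
                               method = c("spearman", "pearson"),
                               threshold = 0.3, min_rows = 10) {
  method <- match.arg(method)
  if (nrow(table) < min_rows) {
    phon_stop("invalidInput", "need >= %d rows for the correlation screen",
              min_rows)
  }
  all_cols <- c(mfcc_columns, other_columns)
  constant <- vapply(all_cols, function(cn) stats::sd(table[[cn]]) == 0,
                     logical(1))
  if (any(constant)) {
    phon_warn("constant column(s) %s: correlations set to 0",
              paste(all_cols[constant], collapse = ", "))
  }
  m <- matrix(0, length(other_columns), length(mfcc_columns),
              dimnames = list(other_columns, mfcc_columns))
  for (oc in other_columns) {
    for (mc in mfcc_columns) {
      if (!constant[[oc]] && !constant[[mc]]) {
        m[oc, mc] <- cor(table[[oc]], table[[mc]], method = method)
      }
    }
  }
  retained <- rownames(m)[apply(abs(m), 1, max) > threshold]
  structure(list(matrix = m[retained, , drop = FALSE], full_matrix = m,
                 retained = retained, method = method,
                 threshold = threshold),
            class = "correlation_screen")
}

#' Linear-model selection by AIC
#'
#' Fits `response ~ factors` by least squares for every candidate factor
#' set and returns the fit minimizing `AIC = n log(RSS/n) + 2 (p + 1)`
#' (`p` = number of estimated coefficients). Rows with missing values are
#' dropped listwise. With `aicc = TRUE` the small-sample corrected AICc is
#' used instead.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param candidate_factor_sets list of character vectors (use
#'   `character(0)` for the intercept-only model); defaults to all subsets
#'   of the supplied `factors`.
#' @param factors pool used to build the default candidate list.
#' @param aicc use the small-sample correction.
#' @return object of class `model_selection`: `best` (a `model_fit`) and
#'   `fits` (all candidates). Each `model_fit` holds `factor_set`,
#'   `coefficients` (with SE, t, p), `rss`, `n`, `aic`.
#' @export
ols_aic_select <- function(table, response, candidate_factor_sets = NULL,
                           factors = c("sex", "group", "age"),
                           aicc = FALSE) {
  if (is.null(candidate_factor_sets)) {
    candidate_factor_sets <- all_subsets(factors)
  }
  fits <- lapply(candidate_factor_sets, function(fset) {
    cols <- c(response, fset)
    dat <- table[stats::complete.cases(table[, cols, drop = FALSE]),
                 cols, drop = FALSE]
    form <- if (length(fset) == 0) {
      stats::as.formula(paste(response, "~ 1"))
    } else {
      stats::as.formula(paste(response, "~", paste(fset, collapse = " + ")))
    }
    fit <- lm(form, data = dat)
    p <- length(coef(fit))
    if (fit$rank < p || anyNA(coef(fit))) {
      phon_stop("rankDeficient", "design matrix not full rank for {%s}",
                paste(fset, collapse = ", "))
    }
    n <- nrow(dat)
    rss <- sum(stats::residuals(fit)^2)
    aic <- n * log(rss / n) + 2 * (p + 1)
    if (aicc) aic <- aic + 2 * (p + 1) * (p + 2) / (n - p - 2)
    sm <- summary(fit)$coefficients
    structure(list(response = response, factor_set = fset,
                   coefficients = sm, rss = rss, n = n, aic = aic),
              class = "model_fit")
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  structure(list(best = fits[[which.min(aics)]], fits = fits),
            class = "model_selection")
}

all_subsets <- function(v) {
  out <- list(character(0))
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via a linear model on the group
#' factor; p-value from the F distribution. The degenerate case (zero
#' within-group variance with equal means) returns `F = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 groups of >= 2 values each).
#' @return list: `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    phon_stop("invalidInput", "need >= 2 groups with >= 2 values each")
  }
  dat <- data.frame(y = values, g = groups)
  # degenerate input: no variation at all -> no evidence either way
  if (max(values) - min(values) < 1e-12) {
    return(list(f_statistic = 0, p_value = 1,
                df_between = nlevels(groups) - 1L,
                df_within = length(values) - nlevels(groups)))
  }
  tab <- anova(lm(y ~ g, data = dat))
  f <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  list(f_statistic = f, p_value = p,
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Descriptive mean/SD table by grouping cells
#'
#' One row per populated grouping cell, with per-metric mean and SD plus the
#' cell size.
#'
#' @param table data.frame.
#' @param metrics character vector of metric column names.
#' @param by character vector of grouping column names.
#' @return data.frame with columns `by`, `n`, and `<metric>_mean`,
#'   `<metric>_sd` per metric.
#' @export
descriptive_table <- function(table, metrics,
                              by = c("dataset", "sex", "group")) {
  by <- intersect(by, names(table))
  if (length(by) == 0) phon_stop("invalidInput", "no grouping columns present")
  key <- interaction(table[, by, drop = FALSE], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    sub <- table[key == lv, , drop = FALSE]
    cell <- sub[1, by, drop = FALSE]
    stats <- lapply(metrics, function(m) {
      v <- sub[[m]]
      out <- data.frame(mean(v, na.rm = TRUE),
                        if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
      names(out) <- paste0(m, c("_mean", "_sd"))
      out
    })
    cbind(cell, n = nrow(sub), do.call(cbind, stats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
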