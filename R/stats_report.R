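## Group-comparison battery and the synthetic ontogeny experiment report.

#' Specification of a group comparison
#'
#' @param design One of `"ttest"`, `"paired_ttest"`, `"anova1"`,
#'   `"anova2_rm"`, `"kruskal_wallis"`, `"ks"`.
#' @param factors Character vector of factor column names (one for one-way
#'   designs; two for `anova2_rm`, the first treated as the within-subject
#'   factor).
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` or `"bonferroni"`; Bonferroni divides alpha by
#'   `n_comparisons`, the explicitly declared size of the comparison family.
#' @param posthoc `"none"` or `"tukey_hsd"` (Tukey's honestly significant
#'   difference; for `anova2_rm` computed on estimated marginal means of the
#'   first factor).
#' @param transform `"identity"` or `"log_dff_plus_1"` (natural log of
#'   value + 1, the compression used for dF/F statistics).
#' @param n_comparisons Declared comparison-family size for Bonferroni.
#' @return An object of class `group_comparison_spec`.
#' @export
group_comparison_spec <- function(design = c("ttest", "paired_ttest", "anova1",
                                             "anova2_rm", "kruskal_wallis", "ks"),
                                  factors, alpha = 0.05,
                                  correction = c("none", "bonferroni"),
                                  posthoc = c("none", "tukey_hsd"),
                                  transform = c("identity", "log_dff_plus_1"),
                                  n_comparisons = 1L) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  posthoc <- match.arg(posthoc)
  transform <- match.arg(transform)
  check_number(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  check_number(n_comparisons, "n_comparisons", positive = TRUE)
  if (missing(factors) || !length(factors)) stop_invalid("`factors` required")
  if (design == "anova2_rm" && length(factors) < 2L) {
    stop_invalid("anova2_rm needs two factors (within-subject factor first)")
  }
  structure(list(design = design, factors = factors, alpha = alpha,
                 correction = correction, posthoc = posthoc,
                 transform = transform,
                 n_comparisons = as.integer(n_comparisons)),
            class = "group_comparison_spec")
}

apply_transform <- function(values, transform) {
  if (transform == "log_dff_plus_1") {
    if (any(values <= -1, na.rm = TRUE)) {
      stop_invalid("log(dFF + 1) undefined for values <= -1")
    }
    log1p(values)
  } else values
}

#' Run one group comparison
#'
#' Applies the declared transform, runs the named test on the `value`
#' column grouped by the declared factors, and attaches a Tukey HSD
#' post-hoc table when requested. Repeated-measures designs (`paired_ttest`,
#' `anova2_rm`) require a `subject` column linking observations; the
#' two-way repeated-measures ANOVA is fit as a mixed design with subject as
#' the repeated unit (`aov` with `Error(subject/within-factor)`).
#'
#' @param data Tidy data frame with a numeric `value` column, the declared
#'   factor columns, and `subject` for repeated designs.
#' @param spec A [group_comparison_spec()].
#' @return An object of class `comparison_result`: `test`, `statistic`,
#'   `p_value`, `df`, `posthoc_table` (when requested), `transform`,
#'   `n_per_group`, `alpha_adjusted`, `significant`.
#' @export
compare_groups <- function(data, spec) {
  if (!inherits(spec, "group_comparison_spec")) {
    stop_invalid("`spec` must be a group_comparison_spec")
  }
  if (!"value" %in% names(data)) stop_invalid("`data` needs a `value` column")
  missing_f <- setdiff(spec$factors, names(data))
  if (length(missing_f)) {
    stop_invalid("missing factor column(s): %s", paste(missing_f, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[c("value", spec$factors)]), ,
               drop = FALSE]
  f1 <- factor(data[[spec$factors[1]]])
  counts <- table(f1)
  if (any(counts < 2L)) stop_invalid("every cell needs >= 2 observations")
  y <- apply_transform(data$value, spec$transform)
  alpha_adj <- if (spec$correction == "bonferroni") {
    spec$alpha / spec$n_comparisons
  } else spec$alpha

  posthoc_table <- NULL
  res <- switch(spec$design,
    ttest = {
      if (nlevels(f1) != 2L) stop_invalid("t-test needs exactly 2 groups")
      tt <- stats::t.test(y ~ f1)
      list(test = "Student t-test", statistic = unname(tt$statistic),
           p = tt$p.value, df = unname(tt$parameter))
    },
    paired_ttest = {
      if (!"subject" %in% names(data)) stop_invalid("paired design needs `subject`")
      if (nlevels(f1) != 2L) stop_invalid("paired t-test needs exactly 2 groups")
      lv <- levels(f1)
      a <- data[f1 == lv[1], ]; b <- data[f1 == lv[2], ]
      m <- match(a$subject, b$subject)
      if (anyNA(m)) stop_invalid("unpaired subjects in paired design")
      ya <- apply_transform(a$value, spec$transform)
      yb <- apply_transform(b$value[m], spec$transform)
      tt <- stats::t.test(ya, yb, paired = TRUE)
      list(test = "paired t-test", statistic = unname(tt$statistic),
           p = tt$p.value, df = unname(tt$parameter))
    },
    anova1 = {
      fit <- stats::aov(y ~ f1)
      sm <- summary(fit)[[1]]
      if (spec$posthoc == "tukey_hsd") {
        tk <- stats::TukeyHSD(fit)$f1
        posthoc_table <- data.frame(contrast = rownames(tk),
                                    diff = tk[, "diff"],
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL)
      }
      list(test = "one-way ANOVA", statistic = sm[["F value"]][1],
           p = sm[["Pr(>F)"]][1],
           df = c(sm[["Df"]][1], sm[["Df"]][nrow(sm)]))
    },
    anova2_rm = {
      if (!"subject" %in% names(data)) stop_invalid("repeated design needs `subject`")
      f2 <- factor(data[[spec$factors[2]]])
      d <- data.frame(y = y, f1 = f1, f2 = f2, subject = factor(data$subject))
      fit <- stats::aov(y ~ f1 * f2 + Error(subject / f1), data = d)
      # embed the data in the stored call so post-hoc re-fits are self-contained
      attr(fit, "call")$data <- d
      sms <- summary(fit)
      rows <- do.call(rbind, lapply(sms, function(s) {
        tab <- s[[1]]
        data.frame(term = trimws(rownames(tab)), F = tab[["F value"]],
                   p = tab[["Pr(>F)"]], df = tab[["Df"]])
      }))
      rows <- rows[!is.na(rows$F), ]
      main <- rows[rows$term == "f1", ]
      if (spec$posthoc == "tukey_hsd") {
        emm <- suppressMessages(emmeans::emmeans(fit, "f1"))
        pr <- as.data.frame(suppressMessages(
          graphics::pairs(emm, adjust = "tukey")))
        posthoc_table <- data.frame(contrast = pr$contrast,
                                    diff = pr$estimate, p_adj = pr$p.value)
      }
      list(test = "two-way repeated-measures ANOVA",
           statistic = main$F[1], p = main$p[1], df = main$df[1],
           terms = rows)
    },
    kruskal_wallis = {
      kw <- stats::kruskal.test(y ~ f1)
      if (spec$posthoc == "tukey_hsd") {
        # rank-based pairwise follow-up with Tukey-style family adjustment
        fit <- stats::aov(rank(y) ~ f1)
        tk <- stats::TukeyHSD(fit)$f1
        posthoc_table <- data.frame(contrast = rownames(tk),
                                    diff = tk[, "diff"],
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL)
      }
      list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
           p = kw$p.value, df = unname(kw$parameter))
    },
    ks = {
      if (nlevels(f1) != 2L) stop_invalid("K-S test needs exactly 2 groups")
      lv <- levels(f1)
      ks <- suppressWarnings(stats::ks.test(y[f1 == lv[1]], y[f1 == lv[2]]))
      list(test = "Kolmogorov-Smirnov", statistic = unname(ks$statistic),
           p = ks$p.value, df = NA_real_)
    }
  )
  structure(
    list(test = res$test, statistic = res$statistic, p_value = res$p,
         df = res$df, posthoc_table = posthoc_table,
         terms = res$terms, transform = spec$transform,
         n_per_group = as.integer(counts), groups = names(counts),
         alpha_adjusted = alpha_adj,
         significant = res$p < alpha_adj),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.3g (alpha %.3g)%s\n",
              x$test, x$statistic, x$p_value, x$alpha_adjusted,
              if (x$significant) " *" else ""))
  if (!is.null(x$posthoc_table)) {
    cat("  post-hoc (Tukey HSD):\n")
    print(x$posthoc_table, row.names = FALSE)
  }
  invisible(x)
}

nonparametric_counterpart <- function(design) {
  switch(design,
    ttest = "kruskal_wallis",         # 2 groups: K-W == Wilcoxon rank-sum family
    paired_ttest = "wilcoxon_signed_rank",
    anova1 = "kruskal_wallis",
    anova2_rm = "kruskal_wallis",
    kruskal_wallis = "kruskal_wallis",
    ks = "ks")
}

#' Dual parametric/nonparametric analysis
#'
#' Runs the declared parametric test on transformed data and its
#' nonparametric counterpart on the raw data (Wilcoxon for t-tests,
#' Kruskal-Wallis for ANOVA designs; for the two-way repeated-measures
#' design the counterpart is Kruskal-Wallis on the first declared factor,
#' there being no standard nonparametric mixed two-way equivalent). Flags a
#' disagreement whenever the two arms differ in significance at the
#' adjusted alpha.
#'
#' @param data,spec As [compare_groups()].
#' @return List with `parametric`, `nonparametric` (both
#'   `comparison_result`) and `disagreement` (logical).
#' @export
dual_analysis <- function(data, spec) {
  par_res <- compare_groups(data, spec)
  np_design <- nonparametric_counterpart(spec$design)
  raw_spec <- spec
  raw_spec$transform <- "identity"
  raw_spec$posthoc <- "none"
  np_res <- if (np_design == "wilcoxon_signed_rank") {
    f1 <- factor(data[[spec$factors[1]]])
    lv <- levels(f1)
    a <- data[f1 == lv[1], ]; b <- data[f1 == lv[2], ]
    m <- match(a$subject, b$subject)
    if (anyNA(m)) stop_invalid("unpaired subjects in paired design")
    wt <- suppressWarnings(stats::wilcox.test(a$value, b$value[m], paired = TRUE))
    structure(list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
                   p_value = wt$p.value, df = NA_real_, posthoc_table = NULL,
                   transform = "identity",
                   n_per_group = as.integer(table(f1)), groups = lv,
                   alpha_adjusted = par_res$alpha_adjusted,
                   significant = wt$p.value < par_res$alpha_adjusted),
              class = "comparison_result")
  } else {
    raw_spec$design <- np_design
    compare_groups(data, raw_spec)
  }
  list(parametric = par_res, nonparametric = np_res,
       disagreement = par_res$significant != np_res$significant)
}

#' Run the full synthetic ontogeny experiment
#'
#' End-to-end: generates a multi-age dataset from `config`, analyzes each
#' arm — one-way ANOVA with Tukey post-hoc on VOR gain and NMJ % area
#' across ages, paired per-neuron dF/F differences with t-tests and
#' bootstrapped SDs for consecutive age pairs — and (optionally) writes
#' tidy CSV tables plus one JSON summary. Fully reproducible per seed; no
#' timestamps enter the outputs.
#'
#' @param config Ontogeny config (see [ontogeny_config_plateau()]).
#' @param seed Integer seed.
#' @param out_dir Optional output directory for CSV/JSON files.
#' @return List with the dataset, per-arm `comparison_result`s
#'   (`gain_anova`, `nmj_anova`, `dff_pair_tests`), and the Tukey tables.
#' @export
run_ontogeny_experiment <- function(config = ontogeny_config_plateau(),
                                    seed = 1L, out_dir = NULL) {
  ds <- generate_ontogeny_dataset(config, seed = seed)
  ages <- config$ages

  gain_data <- data.frame(value = ds$behavior$gain, age = factor(ds$behavior$age))
  gain_spec <- group_comparison_spec("anova1", factors = "age",
                                     posthoc = "tukey_hsd")
  gain_anova <- compare_groups(gain_data, gain_spec)

  nmj_data <- data.frame(value = ds$nmj$percent_area, age = factor(ds$nmj$age))
  nmj_anova <- compare_groups(nmj_data, group_comparison_spec(
    "anova1", factors = "age", posthoc = "tukey_hsd"))

  # longitudinal dF/F: per-neuron paired differences for consecutive ages
  dff_pair_tests <- list()
  for (i in seq_len(length(ages) - 1L)) {
    a <- ages[i]; b <- ages[i + 1L]
    da <- ds$tipm[ds$tipm$age == a, c("neuron", "dff")]
    db <- ds$tipm[ds$tipm$age == b, c("neuron", "dff")]
    names(da) <- names(db) <- c("neuron_id", "mean_dff")
    paired <- pair_longitudinal(da, db,
                                data.frame(id_a = da$neuron_id,
                                           id_b = da$neuron_id))
    diffs <- paired$pairs$difference
    tt <- stats::t.test(diffs)
    dff_pair_tests[[paste0(a, "-", b)]] <- list(
      ages = c(a, b), n = length(diffs), mean_difference = mean(diffs),
      p_value = tt$p.value,
      boot_sd_mean = bootstrap_sd(diffs, statistic = mean, n_boot = 60,
                                  seed = seed + i)
    )
  }

  report <- list(seed = seed, config = config,
                 gain_anova = gain_anova, nmj_anova = nmj_anova,
                 dff_pair_tests = dff_pair_tests)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ds$behavior, file.path(out_dir, "behavior_gains.csv"),
                     row.names = FALSE)
    utils::write.csv(ds$tipm, file.path(out_dir, "tipm_dff.csv"),
                     row.names = FALSE)
    utils::write.csv(ds$nmj, file.path(out_dir, "nmj_percent_area.csv"),
                     row.names = FALSE)
    summary_json <- list(
      seed = seed,
      gain_anova = list(p = gain_anova$p_value, F = gain_anova$statistic,
                        posthoc = gain_anova$posthoc_table),
      nmj_anova = list(p = nmj_anova$p_value, F = nmj_anova$statistic),
      dff_pairs = lapply(dff_pair_tests, function(x) {
        x[c("ages", "n", "mean_difference", "p_value", "boot_sd_mean")]
      })
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(list(dataset = ds), report)
}
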