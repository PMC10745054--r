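#' Percent TMWL reduction versus the untreated control
#'
#' For one membrane, computes each formulation's waterproofing effect as the
#' percent reduction of transmucosal water loss relative to the untreated
#' control membrane:
#' \eqn{\mathrm{reduction} = (TMWL_{control} - TMWL_{treated}) /
#' TMWL_{control} \times 100}.
#' The control is the mean over control replicates; each formulation's
#' treated value is the mean over its replicates.
#'
#' @param panel A `tmwl_panel` data frame (see [read_tmwl_table()] /
#'   [tmwl_reference_panel()]).
#' @param membrane Membrane label to screen.
#' @return A data frame of class `reduction_result` with one row per
#'   non-control formulation: `membrane`, `formulation`, `class`,
#'   `control_tmwl`, `treated_tmwl`, `reduction_pct`, in the panel's
#'   formulation order.
#' @examples
#' percent_reduction(tmwl_reference_panel(), "nuclepore")
#' @export
percent_reduction <- function(panel, membrane) {
  stopifnot(is.data.frame(panel),
            all(c("membrane", "formulation", "tmwl") %in% names(panel)))
  if (is.null(panel$is_control)) panel$is_control <- panel$formulation == "control"
  if (is.null(panel$class)) panel$class <- NA_character_
  rows <- panel[panel$membrane == membrane, , drop = FALSE]
  if (!nrow(rows)) stop("no rows for membrane '", membrane, "'",
                        call. = FALSE)
  ctrl <- rows$tmwl[rows$is_control]
  if (!length(ctrl)) {
    stop("no control row for membrane '", membrane,
         "'; cannot compute percent reduction", call. = FALSE)
  }
  control <- mean(ctrl)
  if (!(control > 0)) {
    stop("control TMWL must be positive", call. = FALSE)
  }
  treated <- rows[!rows$is_control, , drop = FALSE]
  forms <- unique(treated$formulation)
  out <- do.call(rbind, lapply(forms, function(f) {
    sub <- treated[treated$formulation == f, , drop = FALSE]
    tw <- mean(sub$tmwl)
    data.frame(membrane = membrane, formulation = f, class = sub$class[1],
               control_tmwl = control, treated_tmwl = tw,
               reduction_pct = (control - tw) / control * 100,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("reduction_result", "data.frame")
  out
}

#' Rank formulations by waterproofing effect
#'
#' Orders reduction results by descending percent reduction, optionally
#' within formulation class. The sort is stable: equal reductions keep
#' their input order.
#'
#' @param results A `reduction_result` data frame from
#'   [percent_reduction()].
#' @param by_class If `TRUE`, rank within each formulation class
#'   (classes keep their first-appearance order).
#' @return The reordered data frame with a `rank` column (per class when
#'   `by_class`).
#' @export
rank_formulations <- function(results, by_class = FALSE) {
  stopifnot(is.data.frame(results), "reduction_pct" %in% names(results))
  if (!nrow(results)) return(results)
  if (by_class && "class" %in% names(results)) {
    cls <- unique(results$class)
    out <- do.call(rbind, lapply(cls, function(cl) {
      sub <- results[results$class %in% cl, , drop = FALSE]
      sub <- sub[order(-sub$reduction_pct), , drop = FALSE]  # stable
      sub$rank <- seq_len(nrow(sub))
      sub
    }))
  } else {
    out <- results[order(-results$reduction_pct), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Cross-membrane TMWL regression
#'
#' Ordinary least-squares regression of tissue-membrane water loss on
#' surrogate-membrane water loss over matched formulations, quantifying how
#' well the synthetic surrogate predicts the tissue's response to a
#' waterproofing formulation. The direction is tissue ~ surrogate (slope and
#' intercept are reported in that convention); R-squared itself is
#' direction-invariant.
#'
#' @param surrogate_tmwl TMWL on the surrogate membrane, g/(m2 h).
#' @param tissue_tmwl Matched TMWL on the tissue membrane, g/(m2 h).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `pearson_r`, `r2`, `n`, `fitted`, `residuals`.
#' @examples
#' panel <- tmwl_reference_panel()
#' wide <- tmwl_pairs(panel, "nuclepore", "sublingual_mucosa")
#' cross_membrane_regression(wide$surrogate_tmwl, wide$tissue_tmwl)$r2
#' @export
cross_membrane_regression <- function(surrogate_tmwl, tissue_tmwl) {
  stopifnot(length(surrogate_tmwl) == length(tissue_tmwl))
  n <- length(surrogate_tmwl)
  if (n < 3) stop("regression needs at least 3 pairs", call. = FALSE)
  if (stats::var(surrogate_tmwl) == 0) {
    stop("surrogate TMWL values have zero variance; regression is ",
         "degenerate", call. = FALSE)
  }
  fit <- stats::lm(tissue_tmwl ~ surrogate_tmwl)
  cf <- stats::coef(fit)
  ss_tot <- sum((tissue_tmwl - mean(tissue_tmwl))^2)
  r <- if (ss_tot > 0) stats::cor(surrogate_tmwl, tissue_tmwl) else NA_real_
  r2 <- r^2   # identical to 1 - SSres/SStot for simple OLS with intercept
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         pearson_r = unname(r), r2 = unname(r2), n = n,
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::resid(fit))),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Cross-membrane regression (n = %d)\n", x$n))
  cat(sprintf("  tissue = %.4g + %.4g x surrogate\n", x$intercept, x$slope))
  cat(sprintf("  r = %.4f, R2 = %.4f\n", x$pearson_r, x$r2))
  invisible(x)
}

#' Pair formulation TMWL values across two membranes
#'
#' Extracts the matched (surrogate, tissue) TMWL values of the non-control
#' formulations present on both membranes, averaging replicates, ready for
#' [cross_membrane_regression()].
#'
#' @param panel A `tmwl_panel` data frame.
#' @param surrogate,tissue Membrane labels.
#' @return A data frame with `formulation`, `class`, `surrogate_tmwl`,
#'   `tissue_tmwl`.
#' @export
tmwl_pairs <- function(panel, surrogate, tissue) {
  stopifnot(is.data.frame(panel))
  if (is.null(panel$is_control)) panel$is_control <- panel$formulation == "control"
  if (is.null(panel$class)) panel$class <- NA_character_
  treated <- panel[!panel$is_control, , drop = FALSE]
  mean_by <- function(memb) {
    sub <- treated[treated$membrane == memb, , drop = FALSE]
    stats::aggregate(tmwl ~ formulation, data = sub, FUN = mean)
  }
  a <- mean_by(surrogate)
  b <- mean_by(tissue)
  common <- intersect(a$formulation, b$formulation)
  # keep the panel's formulation order
  common <- unique(treated$formulation)[unique(treated$formulation) %in% common]
  cls <- vapply(common, function(f) {
    treated$class[treated$formulation == f][1]
  }, character(1))
  data.frame(formulation = common, class = unname(cls),
             surrogate_tmwl = a$tmwl[match(common, a$formulation)],
             tissue_tmwl = b$tmwl[match(common, b$formulation)],
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric comparison of two or more groups of permeation parameters
#' (or any measurements) by the Kruskal-Wallis rank-sum test, with midrank
#' handling of ties and the standard tie correction. The p-value uses the
#' chi-square approximation with (number of groups - 1) degrees of freedom;
#' an exact permutation p-value is available for small samples.
#'
#' @param groups A list of numeric vectors, one per group (>= 2 non-empty
#'   groups, total n >= 3).
#' @param exact_permutations If > 0, also estimate a permutation p-value
#'   from that many random reassignments of observations to groups
#'   (seeded by `seed`).
#' @param seed Seed for the permutation resampling.
#' @return An object of class `group_test_result`: list with `h_statistic`,
#'   `p_value`, `df`, `group_sizes`, `tie_corrected`, `all_identical`, and
#'   `p_permutation` (`NA` unless requested).
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$h_statistic  # 27/7
#' @export
kruskal_wallis <- function(groups, exact_permutations = 0, seed = 1) {
  stopifnot(is.list(groups))
  if (length(groups) < 2 || any(!lengths(groups))) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total",
                          call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(h_statistic = 0, p_value = 1, df = length(groups) - 1L,
                group_sizes = lengths(groups), tie_corrected = TRUE,
                all_identical = TRUE, p_permutation = NA_real_)
    class(res) <- "group_test_result"
    return(res)
  }
  kt <- stats::kruskal.test(x, g)
  p_perm <- NA_real_
  if (exact_permutations > 0) {
    p_perm <- kw_permutation_p(x, lengths(groups),
                               h_obs = unname(kt$statistic),
                               n_perm = exact_permutations, seed = seed)
  }
  res <- list(h_statistic = unname(kt$statistic),
              p_value = unname(kt$p.value),
              df = unname(kt$parameter),
              group_sizes = lengths(groups),
              tie_corrected = anyDuplicated(x) > 0,
              all_identical = FALSE,
              p_permutation = p_perm)
  class(res) <- "group_test_result"
  res
}

# Permutation reference distribution for the Kruskal-Wallis H statistic:
# ranks are fixed under permutation, so only group rank-sums change.
kw_permutation_p <- function(x, sizes, h_obs, n_perm = 1e4, seed = 1) {
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  h_of <- function(rr) {
    s <- vapply(seq_along(sizes),
                function(i) sum(rr[starts[i]:ends[i]]), numeric(1))
    (12 / (n * (n + 1)) * sum(s^2 / sizes) - 3 * (n + 1)) / tie_corr
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  h_null <- vapply(seq_len(n_perm), function(i) h_of(sample(r)), numeric(1))
  # add-one estimator: the observed assignment counts as one permutation
  (sum(h_null >= h_obs - 1e-12) + 1) / (n_perm + 1)
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank test: H = %.4f, df = %d, p = %.4g\n",
              x$h_statistic, x$df, x$p_value))
  cat("  group sizes:", paste(x$group_sizes, collapse = ", "),
      if (x$tie_corrected) "(tie-corrected)" else "", "\n")
  if (!is.na(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g\n", x$p_permutation))
  }
  invisible(x)
}
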